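#' Surrogate ligand-receptor score between cell states
#'
#' Scores directed sender -> receiver state pairs through surrogate
#' gene pairs in which a synthesizing enzyme (or ligand) marks the sender
#' side and a receptor marks the receiver side -- e.g. TH -> ADRB1 for
#' adrenergic and CHAT -> CHRM2 for cholinergic signaling. A pair is
#' considered expressed when the sender state expresses the sender gene in
#' at least `min_frac` of its cells and likewise the receiver; expressed
#' pairs score the mean of the two mean expressions, others score exactly
#' 0. A multiplicative form (`method = "product"`) is available; it
#' preserves ranking monotonicity but penalizes unbalanced pairs harder.
#'
#' @param profiles A [build_profiles()] reference.
#' @param pairs data.frame with columns `sender_gene`, `receiver_gene`,
#'   `label`.
#' @param senders,receivers Character vectors of state labels.
#' @param min_frac Minimum fraction of expressing cells on both sides.
#' @param method `"mean"` (default) or `"product"` combination of the two
#'   mean expressions.
#' @return data.frame of class `lr_score_table`: `sender_state`,
#'   `receiver_state`, `pair`, `score`, `expressed_flag`.
#' @export
lr_score <- function(profiles, pairs, senders, receivers, min_frac = 0.1,
                     method = c("mean", "product")) {
  method <- match.arg(method)
  stopifnot(inherits(profiles, "state_profiles"),
            all(c("sender_gene", "receiver_gene", "label") %in% names(pairs)))
  check_profile_subset(profiles,
                       c(pairs$sender_gene, pairs$receiver_gene),
                       c(senders, receivers))
  grid <- expand.grid(pair = seq_len(nrow(pairs)),
                      receiver_state = receivers, sender_state = senders,
                      stringsAsFactors = FALSE)
  mu <- profiles$mean_expr
  fr <- profiles$frac_expr
  sg <- pairs$sender_gene[grid$pair]
  rg <- pairs$receiver_gene[grid$pair]
  mu_s <- mu[cbind(sg, grid$sender_state)]
  mu_r <- mu[cbind(rg, grid$receiver_state)]
  flag <- fr[cbind(sg, grid$sender_state)] >= min_frac &
    fr[cbind(rg, grid$receiver_state)] >= min_frac
  score <- ifelse(flag,
                  if (method == "mean") (mu_s + mu_r) / 2 else mu_s * mu_r,
                  0)
  out <- data.frame(sender_state = grid$sender_state,
                    receiver_state = grid$receiver_state,
                    pair = pairs$label[grid$pair],
                    score = score, expressed_flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("lr_score_table", "data.frame")
  out
}

#' Rank ligand-receptor interactions
#'
#' Stable sort by decreasing score with dense ranks (equal scores share a
#' rank; the next distinct score takes the next integer).
#'
#' @param table An [lr_score()] table.
#' @return The table sorted by score with a `rank` column appended.
#' @export
rank_interactions <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  ord <- order(-table$score)            # radix: stable for ties
  out <- table[ord, , drop = FALSE]
  out$rank <- cumsum(!duplicated(out$score))
  rownames(out) <- NULL
  out
}
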