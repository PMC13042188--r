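# Shared test utilities: sequence similarity and subtype matching against
# ground truth.

kendall_tau <- function(a, b) {
  cor(match(seq_along(a), a), match(seq_along(b), b), method = "kendall")
}

# best assignment of fitted subtypes to true subtypes by total Kendall tau;
# returns list(perm, taus) where perm[fitted] = matched truth index
match_subtypes <- function(fitted_seqs, true_seqs) {
  C <- length(fitted_seqs)
  K <- outer(seq_len(C), seq_len(length(true_seqs)),
             Vectorize(function(i, j) kendall_tau(fitted_seqs[[i]],
                                                  true_seqs[[j]])))
  if (C == 2 && length(true_seqs) == 2) {
    perm <- if (K[1, 1] + K[2, 2] >= K[1, 2] + K[2, 1]) c(1, 2) else c(2, 1)
  } else {
    perm <- apply(K, 1, which.max)
  }
  list(perm = perm, taus = vapply(seq_len(C), function(i) K[i, perm[i]],
                                  numeric(1)))
}

# subtype labels of a placement mapped onto truth labels (0 stays 0)
map_subtype_labels <- function(placed, perm) {
  ifelse(placed == 0, 0L, perm[pmax(placed, 1L)])
}

# small hand-made visit-pair tibble builder
make_pairs <- function(subtype_bl, subtype_fu, stage_bl = NULL,
                       stage_fu = NULL, dt_years = 1) {
  n <- length(subtype_bl)
  if (is.null(stage_bl)) stage_bl <- rep(0L, n)
  if (is.null(stage_fu)) stage_fu <- rep(0L, n)
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    subtype_bl = subtype_bl,
    stage_bl = stage_bl,
    subtype_fu = subtype_fu,
    stage_fu = stage_fu,
    dt_years = rep_len(dt_years, n)
  )
}
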