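# Shared fixtures, built in code.

# Hand-written METATOOL text: 1 reversible + 2 irreversible reactions,
# 2 internal + 2 external metabolites.
toy3_text <- function() {
  c("# three-reaction linear chain",
    "-ENZREV",
    "r2",
    "",
    "-ENZIRREV",
    "r1 r3",
    "",
    "-METINT",
    "A B",
    "",
    "-METEXT",
    "Sext Pext",
    "",
    "-CAT",
    "r1 : Sext = A",
    "r2 : A = B",
    "r3 : B = Pext")
}

empty_metatool_text <- function() {
  c("-ENZREV", "-ENZIRREV", "-METINT", "-METEXT", "-CAT")
}

diamond_model <- function() make_toy_network("diamond")$model

# First 50 random-sparse networks (by ascending seed) whose reversible-split
# size fits the brute-force oracle bound of <= 12 reactions.
oracle_sized_networks <- function(n_networks = 50, max_split = 12) {
  out <- list()
  seed <- 0L
  while (length(out) < n_networks) {
    seed <- seed + 1L
    toy <- make_toy_network("random_sparse", n = 4, n_extra = 4,
                            rev_fraction = 0.3, seed = seed)
    if (length(split_reversible(toy$model)$model$reaction_ids) <= max_split)
      out[[length(out) + 1L]] <- toy$model
  }
  out
}

# Independent steady-state / sign-feasibility check on a mode set, using the
# model's float stoichiometry on exact integer coefficients.
expect_valid_modes <- function(modes, model) {
  Ni <- stoich_matrix(model, internal_only = TRUE)
  M <- modes$coeff
  if (nrow(M) > 0) {
    resid <- Ni %*% t(M)
    expect_true(all(resid == 0))
    irr <- !model$reversible
    expect_true(all(M[, irr, drop = FALSE] >= 0))
  }
  sups <- lapply(seq_len(nrow(M)), function(i) which(M[i, ] != 0))
  for (i in seq_along(sups)) for (j in seq_along(sups)) {
    if (i != j)
      expect_false(all(sups[[i]] %in% sups[[j]]) &&
                     length(sups[[i]]) < length(sups[[j]]))
  }
  invisible(modes)
}
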