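# Elementary-mode enumeration.
#
# The enumerator is a nullspace-style double-description tableau over the
# reversible-split (all-irreversible) network, run entirely in exact integer
# arithmetic: start from [I | N^T], eliminate one internal metabolite column
# at a time by nonnegative combination of sign-opposed row pairs, and keep a
# combined row only if the pair is adjacent (no third row's zero set contains
# the pair's common zero set — the combinatorial elementarity test).  The
# surviving first-block rows are the elementary modes of the split cone;
# spurious forward+backward two-cycles are removed, modes are mapped back to
# the signed original space and deduplicated by canonical sign.

.new_mode_set <- function(coeff, reaction_ids) {
  if (is.null(dim(coeff))) coeff <- matrix(coeff, nrow = length(coeff) > 0L)
  if (nrow(coeff) > 0L) colnames(coeff) <- reaction_ids
  structure(list(coeff = coeff, reaction_ids = reaction_ids,
                 count = nrow(coeff)),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("Elementary mode set: %d mode(s) over %d reactions\n",
              x$count, length(x$reaction_ids)))
  invisible(x)
}

#' Number of modes in a mode set
#' @param modes a `mode_set`.
#' @return integer count.
#' @export
n_modes <- function(modes) {
  stopifnot(inherits(modes, "mode_set"))
  modes$count
}

#' Mode coefficient matrix
#'
#' Rows are elementary modes, columns are reactions.  With
#' `canonical = TRUE` each row is rescaled so its smallest nonzero absolute
#' coefficient equals 1 (the canonical scaling); otherwise the exact
#' gcd-reduced integer representation is returned.
#'
#' @param modes a `mode_set`.
#' @param canonical rescale rows to min nonzero |coefficient| = 1.
#' @return numeric matrix (modes x reactions).
#' @export
mode_matrix <- function(modes, canonical = TRUE) {
  stopifnot(inherits(modes, "mode_set"))
  M <- modes$coeff
  if (canonical && nrow(M) > 0L) {
    scale <- apply(M, 1L, function(r) min(abs(r[r != 0])))
    M <- M / scale
  }
  M
}

# Canonical sign/reduction of an integer mode vector in original signed space:
# gcd-reduced; if every support reaction is reversible, the first nonzero
# coefficient is made positive (a fully reversible mode and its negation are
# the same elementary mode).
.canonicalize_mode <- function(v, reversible) {
  v <- .reduce_int(v)
  nz <- which(v != 0)
  if (length(nz) == 0L) return(v)
  if (all(reversible[nz]) && v[nz[1L]] < 0) v <- -v
  v
}

.mode_signature <- function(v) paste(as.integer(v != 0), collapse = "")

# Sort rows deterministically: by support signature, then lexicographically
# by coefficients.
.sort_modes <- function(M) {
  if (nrow(M) <= 1L) return(M)
  sig <- apply(M, 1L, .mode_signature)
  key2 <- apply(M, 1L, paste, collapse = ",")
  M[order(sig, key2), , drop = FALSE]
}

#' Enumerate all elementary modes of a metabolic model
#'
#' An elementary mode is a steady-state flux vector (internal metabolites
#' exactly balanced), feasible in sign (irreversible reactions nonnegative),
#' whose support is minimal: no other steady-state vector uses a proper
#' subset of its reactions.  Enumeration is complete and exact (integer
#' arithmetic throughout); output order is deterministic (sorted by support
#' signature).
#'
#' @param model a valid `metabolic_model` with at least the structure needed
#'   for enumeration (a model with zero reactions yields an empty set).
#' @param max_modes capacity cap; if the working set ever exceeds it an error
#'   is raised rather than truncating silently.  Default `1e7`.
#' @return a `mode_set`; rows of its coefficient matrix are gcd-reduced
#'   integer vectors in the original signed reaction space.
#' @seealso [brute_force_modes()] for the exhaustive oracle on tiny networks.
#' @export
enumerate_elementary_modes <- function(model, max_modes = 1e7) {
  stopifnot(inherits(model, "metabolic_model"))
  nr <- length(model$reaction_ids)
  if (nr == 0L)
    return(.new_mode_set(matrix(0, 0, 0), character(0)))

  split <- split_reversible(model)
  Ni <- .internal_int_matrix(split$model)   # m_int x n_split
  n <- ncol(Ni)
  m <- nrow(Ni)

  # tableau rows: [ mode block (n cols) | residual metabolite block ]
  T <- cbind(diag(n), t(Ni))
  remaining <- seq_len(m)                    # residual column order in T

  while (length(remaining) > 0L) {
    # choose the residual column with fewest sign-opposed pairs
    res <- T[, n + seq_along(remaining), drop = FALSE]
    npos <- colSums(res > 0)
    nneg <- colSums(res < 0)
    pick <- which.min(npos * nneg + (npos + nneg))
    col <- T[, n + pick]

    zero_rows <- which(col == 0)
    pos_rows <- which(col > 0)
    neg_rows <- which(col < 0)

    keep <- T[zero_rows, , drop = FALSE]
    new_rows <- list()
    if (length(pos_rows) && length(neg_rows)) {
      zero_pattern <- T == 0                  # rows x cols logical
      for (a in pos_rows) {
        za <- zero_pattern[a, ]
        for (b in neg_rows) {
          zab <- za & zero_pattern[b, ]
          # adjacency: no third row zero wherever both a and b are zero
          others <- setdiff(seq_len(nrow(T)), c(a, b))
          adjacent <- TRUE
          if (length(others)) {
            cand <- zero_pattern[others, zab, drop = FALSE]
            if (any(rowSums(!cand) == 0L)) adjacent <- FALSE
          }
          if (!adjacent) next
          comb <- abs(col[b]) * T[a, ] + col[a] * T[b, ]
          .check_exact(comb, "mode enumeration")
          new_rows[[length(new_rows) + 1L]] <- .reduce_int(comb)
        }
      }
    }
    if (length(new_rows)) {
      T <- rbind(keep, do.call(rbind, new_rows))
    } else {
      T <- keep
    }
    remaining <- remaining[-pick]
    T <- T[, -(n + pick), drop = FALSE]
    if (nrow(T) > max_modes)
      stop(sprintf("mode enumeration exceeded the capacity cap (%g modes); raise 'max_modes' to continue",
                   max_modes), call. = FALSE)
  }

  if (nrow(T) == 0L)
    return(.new_mode_set(matrix(0, 0, nr,
                                dimnames = list(NULL, model$reaction_ids)),
                         model$reaction_ids))

  V <- T[, seq_len(n), drop = FALSE]         # split-space modes, >= 0
  V <- V[rowSums(V != 0) > 0, , drop = FALSE]

  # drop the forward+backward two-cycles created by reversible splitting
  is_two_cycle <- vapply(seq_len(nrow(V)), function(i) {
    sup <- which(V[i, ] != 0)
    length(sup) == 2L &&
      !is.na(match(sup[2L], split$backward)) &&
      split$forward[match(sup[2L], split$backward)] == sup[1L]
  }, logical(1))
  V <- V[!is_two_cycle, , drop = FALSE]
  if (nrow(V) == 0L)
    return(.new_mode_set(matrix(0, 0, nr,
                                dimnames = list(NULL, model$reaction_ids)),
                         model$reaction_ids))

  # map back to signed original space and deduplicate
  modes <- matrix(0, nrow(V), nr)
  for (i in seq_len(nrow(V)))
    modes[i, ] <- recombine_fluxes(V[i, ], split)
  modes <- t(apply(modes, 1L, .canonicalize_mode,
                   reversible = model$reversible))
  if (nr == 1L) modes <- matrix(modes, ncol = 1L)
  modes <- unique(modes)
  modes <- .sort_modes(modes)
  if (nrow(modes) > max_modes)
    stop(sprintf("mode enumeration exceeded the capacity cap (%g modes)",
                 max_modes), call. = FALSE)
  .new_mode_set(modes, model$reaction_ids)
}

#' Exhaustively enumerate elementary modes (oracle for tiny networks)
#'
#' Definition-level enumeration used to verify [enumerate_elementary_modes()]:
#' every candidate support of the reversible-split network is tested for a
#' one-dimensional, sign-feasible exact nullspace of the restricted internal
#' stoichiometric matrix; supersets of feasible supports are discarded.
#' Intended purely as a verification oracle.
#'
#' @param model a `metabolic_model` with at most 14 reactions after
#'   reversible splitting.
#' @return a `mode_set` identical in content to the enumerator's output.
#' @export
brute_force_modes <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  nr <- length(model$reaction_ids)
  if (nr == 0L)
    return(.new_mode_set(matrix(0, 0, 0), character(0)))
  split <- split_reversible(model)
  n <- length(split$model$reaction_ids)
  if (n > 14L)
    stop("brute_force_modes is limited to models with <= 14 reactions after reversible splitting",
         call. = FALSE)
  Ni <- .internal_int_matrix(split$model)

  # exclude supports containing both directions of one reversible reaction
  pair_mask <- rep(0, n)
  for (j in which(!is.na(split$backward))) {
    pair_mask[split$forward[j]] <- j
    pair_mask[split$backward[j]] <- j
  }

  found_supports <- list()   # logical vectors over split reactions
  found_vectors <- list()
  subsets_by_size <- vector("list", n)
  all_masks <- seq_len(2^n - 1L)
  sizes <- vapply(all_masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1L))) > 0), numeric(1))
  ord <- order(sizes)
  bits <- 2^(0:(n - 1L))

  for (mask in all_masks[ord]) {
    sup <- bitwAnd(mask, bits) > 0
    idx <- which(sup)
    # both-direction supports can never be elementary (contain a 2-cycle)
    pm <- pair_mask[idx]
    if (anyDuplicated(pm[pm > 0])) next
    # minimality: skip supersets of already-found supports
    superset <- FALSE
    for (fs in found_supports) {
      if (all(sup[fs])) { superset <- TRUE; break }
    }
    if (superset) next
    v <- .nullspace_1d(Ni, idx)
    if (is.null(v)) next
    if (any(v == 0)) next            # support must be exactly idx
    if (all(v < 0)) v <- -v
    if (any(v < 0)) next             # sign-infeasible in the split cone
    found_supports[[length(found_supports) + 1L]] <- idx
    full <- numeric(n); full[idx] <- v
    found_vectors[[length(found_vectors) + 1L]] <- full
  }

  if (length(found_vectors) == 0L)
    return(.new_mode_set(matrix(0, 0, nr,
                                dimnames = list(NULL, model$reaction_ids)),
                         model$reaction_ids))

  modes <- matrix(0, length(found_vectors), nr)
  for (i in seq_along(found_vectors))
    modes[i, ] <- recombine_fluxes(found_vectors[[i]], split)
  modes <- t(apply(modes, 1L, .canonicalize_mode,
                   reversible = model$reversible))
  if (nr == 1L) modes <- matrix(modes, ncol = 1L)
  modes <- unique(modes)
  modes <- .sort_modes(modes)
  .new_mode_set(modes, model$reaction_ids)
}

#' Does a mode use a given reaction?
#'
#' @param modes a `mode_set`.
#' @param i mode index (row).
#' @param reaction_id a reaction declared in the model.
#' @return `TRUE` iff the reaction is in the mode's support.
#' @export
mode_contains <- function(modes, i, reaction_id) {
  stopifnot(inherits(modes, "mode_set"))
  j <- match(reaction_id, modes$reaction_ids)
  if (is.na(j))
    stop("unknown reaction id '", reaction_id, "'", call. = FALSE)
  modes$coeff[i, j] != 0
}

#' Mode supports as reaction-id sets
#' @param modes a `mode_set`.
#' @return list of character vectors, one per mode.
#' @export
mode_supports <- function(modes) {
  stopifnot(inherits(modes, "mode_set"))
  apply(modes$coeff, 1L, function(r) modes$reaction_ids[r != 0],
        simplify = FALSE)
}

#' Write a mode set to tab-separated text
#'
#' One mode per row in canonical scaling (smallest nonzero |coefficient| = 1),
#' values as exact rational strings (`"3/2"`), header row of reaction ids.
#'
#' @param modes a `mode_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_modeset <- function(modes, path) {
  stopifnot(inherits(modes, "mode_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(modes$reaction_ids, collapse = "\t"), con)
  if (modes$count > 0L) {
    for (i in seq_len(modes$count)) {
      r <- modes$coeff[i, ]
      den <- min(abs(r[r != 0]))      # canonical scaling denominator
      g <- vapply(r, function(x) max(.gcd2(x, den), 1), numeric(1))
      writeLines(paste(.format_rat(r / g, den / g), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a mode set written by [write_modeset()]
#'
#' @param path path to the tab-separated mode file.
#' @return a `mode_set` (integer-reduced internal representation).
#' @export
read_modeset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  reaction_ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1L)
    return(.new_mode_set(matrix(0, 0, length(reaction_ids),
                                dimnames = list(NULL, reaction_ids)),
                         reaction_ids))
  rows <- lapply(lines[-1], function(ln) {
    toks <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    neg <- startsWith(toks, "-")
    rat <- .parse_rat_vec(sub("^-", "", toks))
    L <- .lcm_vec(rat$den)
    v <- rat$num * (L / rat$den) * ifelse(neg, -1, 1)
    .check_exact(v, "mode deserialization")
    .reduce_int(v)
  })
  M <- do.call(rbind, rows)
  .new_mode_set(M, reaction_ids)
}
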