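# Synthetic data generation.
#
# Toy networks with analytically known elementary-mode sets, synthetic
# per-animal measurements constructed so the organ-balance arithmetic
# recovers a prescribed flux pattern, and synthetic differential-expression
# tables with a known upregulated subset.  Everything is deterministic given
# its seed and written in the same formats the real pipeline reads.

# Build a model from a reaction list: each element list(id, substrates =
# named coefficients (consumed), products = named coefficients, rev).
.build_model <- function(reactions, internal, external,
                         substrates = numeric(0), exchange_map = character(0),
                         gene_map = NULL) {
  mets <- c(internal, external)
  ids <- vapply(reactions, `[[`, character(1), "id")
  num <- matrix(0, length(mets), length(ids),
                dimnames = list(mets, ids))
  for (r in reactions) {
    for (m in names(r$consumes)) num[m, r$id] <- num[m, r$id] - r$consumes[[m]]
    for (m in names(r$produces)) num[m, r$id] <- num[m, r$id] + r$produces[[m]]
  }
  rev <- vapply(reactions, function(r) isTRUE(r$rev), logical(1))
  # reversible-first order so the model round-trips METATOOL exactly
  ord <- order(!rev)
  ids <- ids[ord]; rev <- rev[ord]; num <- num[, ord, drop = FALSE]
  if (is.null(gene_map))
    gene_map <- stats::setNames(as.list(paste0("G_", ids)), ids)
  metabolic_model(
    reaction_ids = ids, reversible = rev,
    metabolite_ids = mets,
    is_internal = c(rep(TRUE, length(internal)), rep(FALSE, length(external))),
    stoich_num = num,
    substrates = substrates, gene_map = gene_map,
    exchange_map = exchange_map)
}

.rx <- function(id, consumes, produces, rev = FALSE)
  list(id = id, consumes = as.list(consumes), produces = as.list(produces),
       rev = rev)

#' Generate a toy metabolic network
#'
#' Families with analytically known elementary-mode counts — `chain(n)` has
#' exactly 1 mode, `diamond` exactly 2, `fan(k)` (one uptake feeding k
#' parallel branch/export pairs) exactly k, `double_diamond` exactly 4, and
#' `cycle_chain` (a chain plus an internal 3-cycle) exactly 2 including one
#' substrate-free cycle — plus a `random_sparse` family (backbone path with
#' random extra reactions; no claimed count, the brute-force oracle decides).
#' Every generated model carries a substrate annotation on its uptake
#' reaction (molecular weight 100 g/mol for clean hand arithmetic), an
#' exchange map over its exchange reactions, and a one-gene-per-reaction gene
#' map (`G_<reaction>`).
#'
#' @param family one of `"chain"`, `"diamond"`, `"fan"`, `"double_diamond"`,
#'   `"cycle_chain"`, `"random_sparse"`.
#' @param n chain length (reactions) for `chain`; internal metabolite count
#'   for `random_sparse`.
#' @param k number of branches for `fan`.
#' @param n_extra extra random reactions for `random_sparse`.
#' @param rev_fraction fraction of reversible reactions (`random_sparse`).
#' @param seed RNG seed (`random_sparse` only).
#' @return list with `model` and `em_count` (`NA` for `random_sparse`).
#' @export
make_toy_network <- function(family = c("chain", "diamond", "fan",
                                        "double_diamond", "cycle_chain",
                                        "random_sparse"),
                             n = 4, k = 3, n_extra = 3, rev_fraction = 0.25,
                             seed = 1) {
  family <- match.arg(family)
  if (family == "chain") {
    if (n < 2) stop("chain needs n >= 2 reactions", call. = FALSE)
    internal <- paste0("M", seq_len(n - 1))
    nodes <- c("Sext", internal, "Pext")
    reactions <- lapply(seq_len(n), function(i)
      .rx(sprintf("r%d", i), stats::setNames(1, nodes[i]),
          stats::setNames(1, nodes[i + 1])))
    model <- .build_model(reactions, internal, c("Sext", "Pext"),
                          substrates = c(r1 = 100),
                          exchange_map = stats::setNames(
                            c("S", "P"), c("r1", sprintf("r%d", n))))
    return(list(model = model, em_count = 1L))
  }
  if (family == "diamond") {
    reactions <- list(
      .rx("up", c(Sext = 1), c(A = 1)),
      .rx("ab", c(A = 1), c(B = 1)),
      .rx("b_out", c(B = 1), c(Bext = 1)),
      .rx("ac", c(A = 1), c(C = 1)),
      .rx("c_out", c(C = 1), c(Cext = 1)))
    model <- .build_model(reactions, c("A", "B", "C"),
                          c("Sext", "Bext", "Cext"),
                          substrates = c(up = 100),
                          exchange_map = c(up = "S", b_out = "B", c_out = "C"))
    return(list(model = model, em_count = 2L))
  }
  if (family == "fan") {
    if (k < 2) stop("fan needs k >= 2 branches", call. = FALSE)
    internal <- c("A", paste0("B", seq_len(k)))
    external <- c("Sext", paste0("X", seq_len(k), "ext"))
    reactions <- c(list(.rx("up", c(Sext = 1), c(A = 1))),
                   unlist(lapply(seq_len(k), function(i) list(
                     .rx(sprintf("br%d", i), c(A = 1),
                         stats::setNames(1, sprintf("B%d", i))),
                     .rx(sprintf("out%d", i),
                         stats::setNames(1, sprintf("B%d", i)),
                         stats::setNames(1, sprintf("X%dext", i)))
                   )), recursive = FALSE))
    emap <- stats::setNames(c("S", paste0("X", seq_len(k))),
                            c("up", sprintf("out%d", seq_len(k))))
    model <- .build_model(reactions, internal, external,
                          substrates = c(up = 100), exchange_map = emap)
    return(list(model = model, em_count = as.integer(k)))
  }
  if (family == "double_diamond") {
    # two diamonds in series: 2 x 2 branch choices = 4 modes
    reactions <- list(
      .rx("up", c(Sext = 1), c(A = 1)),
      .rx("ab1", c(A = 1), c(B1 = 1)),
      .rx("ab2", c(A = 1), c(B2 = 1)),
      .rx("b1d", c(B1 = 1), c(D = 1)),
      .rx("b2d", c(B2 = 1), c(D = 1)),
      .rx("dc1", c(D = 1), c(C1 = 1)),
      .rx("dc2", c(D = 1), c(C2 = 1)),
      .rx("c1_out", c(C1 = 1), c(P1ext = 1)),
      .rx("c2_out", c(C2 = 1), c(P2ext = 1)))
    model <- .build_model(reactions, c("A", "B1", "B2", "D", "C1", "C2"),
                          c("Sext", "P1ext", "P2ext"),
                          substrates = c(up = 100),
                          exchange_map = c(up = "S", c1_out = "P1",
                                           c2_out = "P2"))
    return(list(model = model, em_count = 4L))
  }
  if (family == "cycle_chain") {
    # chain Sext -> A -> B -> Pext plus internal cycle B -> C -> A:
    # one through-chain mode and one substrate-free internal cycle
    reactions <- list(
      .rx("up", c(Sext = 1), c(A = 1)),
      .rx("ab", c(A = 1), c(B = 1)),
      .rx("b_out", c(B = 1), c(Pext = 1)),
      .rx("bc", c(B = 1), c(C = 1)),
      .rx("ca", c(C = 1), c(A = 1)))
    model <- .build_model(reactions, c("A", "B", "C"), c("Sext", "Pext"),
                          substrates = c(up = 100),
                          exchange_map = c(up = "S", b_out = "P"))
    return(list(model = model, em_count = 2L))
  }
  # random_sparse: backbone path over n internal metabolites (every internal
  # metabolite touched by >= 2 reactions), uptake + export, plus n_extra
  # random internal conversions or exports.
  if (n < 2) stop("random_sparse needs n >= 2 internal metabolites",
                  call. = FALSE)
  set.seed(seed)
  internal <- paste0("M", seq_len(n))
  external <- c("Sext", "Pext", "Qext")
  reactions <- c(
    list(.rx("up", c(Sext = 1), c(M1 = 1))),
    lapply(seq_len(n - 1), function(i)
      .rx(sprintf("b%d", i), stats::setNames(1, internal[i]),
          stats::setNames(1, internal[i + 1]))),
    list(.rx("out", stats::setNames(1, internal[n]), c(Pext = 1))))
  for (e in seq_len(n_extra)) {
    coef <- sample(c(1, 1, 2), 1)
    if (stats::runif(1) < 0.3) {
      src <- sample(internal, 1)
      reactions[[length(reactions) + 1L]] <-
        .rx(sprintf("x%d", e), stats::setNames(coef, src), c(Qext = 1))
    } else {
      pair <- sample(internal, 2)
      reactions[[length(reactions) + 1L]] <-
        .rx(sprintf("x%d", e), stats::setNames(coef, pair[1]),
            stats::setNames(1, pair[2]))
    }
  }
  rev <- stats::runif(length(reactions)) < rev_fraction
  for (i in seq_along(reactions)) reactions[[i]]$rev <- rev[i]
  model <- .build_model(reactions, internal, external,
                        substrates = c(up = 100),
                        exchange_map = c(up = "S", out = "P"))
  list(model = model, em_count = NA_integer_)
}

#' Synthesize per-animal measurements realizing a known flux pattern
#'
#' Builds arterial/venous plasma concentrations, flows and body weights such
#' that [exchange_flux()] recovers `true_pattern` plus Gaussian noise.  Noise
#' is added to the venous concentration (so it propagates through the same
#' organ-balance arithmetic as real measurements); its standard deviation is
#' chosen so the resulting flux noise has standard deviation `noise_sd` (flux
#' units).  Optionally a urinary excretion pattern is realized the same way
#' through the urine concentration.
#'
#' @param true_pattern named numeric: release-positive exchange flux per
#'   metabolite, nmol (100 g bw)^-1 min^-1.
#' @param n_animals number of animals (>= 1).
#' @param noise_sd flux-scale noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param group group label for all animals (default `"AL"`).
#' @param urinary_pattern named numeric: urinary excretion rate per
#'   metabolite (default none; realized via urine concentration).
#' @param body_weight body weight in g (default 300).
#' @param plasma_flow renal plasma flow in ml min^-1 (default 3.0, the
#'   observed healthy-rat scale).
#' @param urine_flow urine flow in ml min^-1 (default 0.009).
#' @param arterial_base arterial plasma concentration in nmol ml^-1
#'   (default 500).
#' @return data.frame in [read_animal_table()] layout.
#' @export
make_synthetic_measurements <- function(true_pattern, n_animals, noise_sd = 0,
                                        seed = 1, group = "AL",
                                        urinary_pattern = numeric(0),
                                        body_weight = 300, plasma_flow = 3.0,
                                        urine_flow = 0.009,
                                        arterial_base = 500) {
  stopifnot(n_animals >= 1, noise_sd >= 0,
            !is.null(names(true_pattern)))
  set.seed(seed)
  mets <- names(true_pattern)
  conc_sd <- noise_sd * body_weight / (100 * plasma_flow)
  rows <- list()
  for (a in seq_len(n_animals)) {
    for (m in mets) {
      delta <- true_pattern[[m]] * body_weight / (100 * plasma_flow)
      noise <- if (noise_sd > 0) stats::rnorm(1, 0, conc_sd) else 0
      u_rate <- if (m %in% names(urinary_pattern)) urinary_pattern[[m]] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        animal = sprintf("a%02d", a), group = group, metabolite = m,
        bw_g = body_weight, art_conc = arterial_base,
        ven_conc = arterial_base + delta + noise,
        urine_conc = u_rate * body_weight / (100 * urine_flow),
        urine_flow = urine_flow, plasma_flow = plasma_flow,
        hematocrit = 0.45, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Synthesize a differential-expression table with a known answer
#'
#' Upregulated genes receive the prescribed positive log2 fold change (with
#' small positive jitter) and an adjusted P well below `alpha`; all other
#' genes receive a near-zero log2 fold change and an adjusted P at or above
#' `alpha`, so [select_upregulated()] recovers exactly the prescribed subset.
#'
#' @param genes character vector of gene symbols.
#' @param upregulated subset of `genes` to mark as upregulated.
#' @param effect_log2fc log2 fold change given to upregulated genes
#'   (default 2).
#' @param seed RNG seed.
#' @param alpha significance threshold the table is built around
#'   (default 0.05).
#' @return data.frame with columns `gene`, `log2fc`, `padj`.
#' @export
make_synthetic_expression <- function(genes, upregulated,
                                      effect_log2fc = 2, seed = 1,
                                      alpha = 0.05) {
  stopifnot(all(upregulated %in% genes), effect_log2fc > 0)
  set.seed(seed)
  up <- genes %in% upregulated
  n <- length(genes)
  log2fc <- stats::rnorm(n, 0, 0.1)
  log2fc[up] <- effect_log2fc + abs(stats::rnorm(sum(up), 0, 0.1))
  padj <- alpha + (1 - alpha) * stats::runif(n)
  padj[up] <- alpha * stats::runif(sum(up)) / 10
  data.frame(gene = genes, log2fc = log2fc, padj = padj,
             stringsAsFactors = FALSE)
}

#' Predicted exchange-flux pattern of a structural-flux table
#'
#' Maps a prediction to the measured-metabolite space using the model's
#' exchange map, with uptake reactions negated (release-positive), ready to
#' feed [make_synthetic_measurements()] as a ground-truth pattern.
#'
#' @param pred a `structural_flux_table`.
#' @param model the `metabolic_model` carrying the exchange map.
#' @return named numeric vector, metabolite -> release-positive flux.
#' @export
predicted_exchange_pattern <- function(pred, model) {
  if (length(model$exchange_map) == 0L)
    stop("model has no exchange map", call. = FALSE)
  ext <- !model$is_internal
  out <- vapply(names(model$exchange_map), function(rid) {
    i <- match(rid, pred$reaction)
    col <- model$stoich_num[, rid]
    if (any(ext & col < 0)) -pred$aStruF[i] else pred$aStruF[i]
  }, numeric(1))
  names(out) <- unname(model$exchange_map)
  out
}
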