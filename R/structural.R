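# Structural fluxes.
#
# Each elementary mode i is scored against a biological objective: its
# reaction coefficients c_i^k are normalized by the molecular-weight-weighted
# sum of its substrate uptakes,
#
#     e_i^k = c_i^k / sum_{s in substrates} c_{s,i} * MW_s ,
#
# making yields comparable across substrates of very different size (glucose
# vs. whole protein).  The efficiency of the mode is the ratio of its
# objective yield to the total flux investment,
#
#     eps_i = e_i^objective / sum_k |e_i^k| ,
#
# and the structural flux of reaction k is the efficiency-weighted average of
# its absolute participation over all modes,
#
#     aSF_k = sum_i eps_i * |e_i^k| / sum_i eps_i ,
#
# normalized by the total substrate uptake flux for cross-network comparison:
# aStruF_k = aSF_k / aSF_TotalSub.  All quantities are invariant under
# positive rescaling of any mode.

#' Define a biological objective
#'
#' @param name human-readable objective name (e.g. `"ammonia excretion"`).
#' @param reaction the model reaction whose normalized yield is maximized by
#'   the tissue under this objective (an exchange or synthesis reaction).
#' @return an `objective_spec`.
#' @export
objective_spec <- function(name, reaction) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(reaction), length(reaction) == 1L)
  structure(list(name = name, reaction = reaction), class = "objective_spec")
}

#' Default objective registry
#'
#' Named slots for the biological objectives relevant to kidney metabolism in
#' the postabsorptive state: ammonia excretion, glucose production, ATP
#' maintenance, growth (artificial biomass reaction), urea excretion, protein
#' uptake and breakdown, lactate and free-fatty-acid uptake, and
#' per-amino-acid transport slots (lysine, phenylalanine).  Values are the
#' model reaction ids and must be supplied by the user (here `NA`), since
#' reaction naming is model-specific; any additional user-defined objectives
#' can be appended.
#'
#' @return named character vector, objective name -> reaction id (`NA` until
#'   configured).
#' @export
default_objective_registry <- function() {
  c("ammonia excretion"      = NA_character_,
    "glucose production"     = NA_character_,
    "ATP maintenance"        = NA_character_,
    "growth"                 = NA_character_,
    "urea excretion"         = NA_character_,
    "protein uptake"         = NA_character_,
    "protein breakdown"      = NA_character_,
    "lactate uptake"         = NA_character_,
    "free fatty acid uptake" = NA_character_,
    "lysine transport"       = NA_character_,
    "phenylalanine transport" = NA_character_)
}

#' Read an objective registry from a YAML config
#'
#' @param path YAML file mapping objective name -> reaction id.
#' @return list of [objective_spec()] objects.
#' @export
read_objective_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(names(raw), function(nm) objective_spec(nm, as.character(raw[[nm]])))
}

# Accept either a mode_set or a plain numeric coefficient matrix
# (rows = modes); returns the matrix with reaction-id columns.
.as_mode_coeff <- function(x, model) {
  if (inherits(x, "mode_set")) {
    if (!identical(x$reaction_ids, model$reaction_ids))
      stop("mode set and model disagree on reaction ids", call. = FALSE)
    return(mode_matrix(x, canonical = TRUE))
  }
  M <- as.matrix(x)
  if (ncol(M) != length(model$reaction_ids))
    stop("coefficient matrix must have one column per model reaction",
         call. = FALSE)
  colnames(M) <- model$reaction_ids
  M
}

#' Molecular-weight-normalized yields of elementary modes
#'
#' For every mode, each reaction coefficient is divided by the mode's
#' substrate investment: the sum over substrate uptake reactions of
#' (uptake coefficient) x (substrate molecular weight).  A substrate carried
#' in the producing direction contributes zero to the denominator.  Modes
#' with an all-zero denominator (e.g. internal futile cycles) take up no
#' substrate; they are flagged and get `NA` yields.
#'
#' @param modes a `mode_set` or a numeric coefficient matrix (modes x
#'   reactions).
#' @param model a `metabolic_model` declaring at least one substrate with its
#'   molecular weight.
#' @return list with `yields` (modes x reactions matrix of e values),
#'   `denominator` (per-mode substrate weight, g/mol-scaled), and
#'   `no_substrate` (logical per mode).
#' @export
normalized_yields <- function(modes, model) {
  if (length(model$substrates) == 0L)
    stop("model declares no substrate molecular weights; ",
         "attach them with apply_sidecar()", call. = FALSE)
  C <- .as_mode_coeff(modes, model)
  sub_idx <- match(names(model$substrates), model$reaction_ids)
  uptake <- C[, sub_idx, drop = FALSE]
  uptake[uptake < 0] <- 0                # produced substrate: no contribution
  denom <- as.numeric(uptake %*% model$substrates)
  no_substrate <- denom == 0
  yields <- C / denom                    # rows with denom 0 become Inf/NaN
  yields[no_substrate, ] <- NA_real_
  list(yields = yields, denominator = denom, no_substrate = no_substrate)
}

#' Efficiency of elementary modes toward an objective
#'
#' The ratio of the mode's normalized objective yield to the total normalized
#' flux investment `sum_k |e_i^k|`.  Modes that take up no substrate, or
#' whose objective yield is zero or negative (the objective read as a
#' production ratio), have efficiency 0.
#'
#' @inheritParams normalized_yields
#' @param objective an [objective_spec()].
#' @return numeric vector of per-mode efficiencies (>= 0).
#' @export
efficiency <- function(modes, model, objective) {
  stopifnot(inherits(objective, "objective_spec"))
  j <- match(objective$reaction, model$reaction_ids)
  if (is.na(j))
    stop("objective reaction '", objective$reaction,
         "' is not declared in the model", call. = FALSE)
  ny <- normalized_yields(modes, model)
  eps <- numeric(nrow(ny$yields))
  ok <- !ny$no_substrate
  if (any(ok)) {
    obj_yield <- ny$yields[ok, j]
    invest <- rowSums(abs(ny$yields[ok, , drop = FALSE]))
    e <- obj_yield / invest
    e[obj_yield <= 0] <- 0
    eps[ok] <- e
  }
  eps
}

#' Structural fluxes for one objective
#'
#' Aggregates the active mode set into a per-reaction structural flux: each
#' mode containing the reaction contributes its absolute normalized yield,
#' weighted by the mode's efficiency, and the weighted sum is normalized by
#' the total efficiency.  `aSF_TotalSub` is the summed structural flux of the
#' substrate uptake reactions, and `aStruF = aSF / aSF_TotalSub` makes the
#' values comparable across networks and mode subsets.
#'
#' @inheritParams efficiency
#' @param scenario optional label describing the active mode set (e.g. a gene
#'   restriction); stored in the result.
#' @return a `structural_flux_table`: data.frame with columns `reaction`,
#'   `aSF`, `aStruF`, plus attributes `objective`, `scenario` and
#'   `aSF_total_sub`.
#' @export
structural_fluxes <- function(modes, model, objective, scenario = "all modes") {
  eps <- efficiency(modes, model, objective)
  if (all(eps == 0))
    stop("objective unreachable: no elementary mode in the active set produces '",
         objective$name, "'", call. = FALSE)
  ny <- normalized_yields(modes, model)
  w <- eps / sum(eps)
  E <- abs(ny$yields)
  E[ny$no_substrate, ] <- 0              # eps = 0 there anyway
  aSF <- as.numeric(w %*% E)
  names(aSF) <- model$reaction_ids
  sub_idx <- match(names(model$substrates), model$reaction_ids)
  total_sub <- sum(aSF[sub_idx])
  if (total_sub <= 0)
    stop("total substrate structural flux is zero; aStruF is undefined",
         call. = FALSE)
  out <- data.frame(reaction = model$reaction_ids,
                    aSF = aSF,
                    aStruF = aSF / total_sub,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "objective") <- objective$name
  attr(out, "objective_reaction") <- objective$reaction
  attr(out, "scenario") <- scenario
  attr(out, "aSF_total_sub") <- total_sub
  class(out) <- c("structural_flux_table", "data.frame")
  out
}

#' Scan a list of objectives
#'
#' Computes one structural-flux table per objective.  Objectives reachable by
#' no mode of the active set are reported as unreachable (and excluded from
#' any downstream ranking) rather than dropped.
#'
#' @inheritParams efficiency
#' @param objectives nonempty list of [objective_spec()] objects.
#' @param scenario optional label for the active mode set.
#' @return named list, one element per objective: `list(objective, reachable,
#'   table)` where `table` is `NULL` when unreachable.
#' @export
objective_scan <- function(modes, model, objectives, scenario = "all modes") {
  if (length(objectives) == 0L)
    stop("'objectives' must be nonempty", call. = FALSE)
  out <- lapply(objectives, function(obj) {
    tab <- tryCatch(structural_fluxes(modes, model, obj, scenario = scenario),
                    error = function(e) {
                      if (grepl("objective unreachable", conditionMessage(e)))
                        NULL
                      else stop(e)
                    })
    list(objective = obj$name, reachable = !is.null(tab), table = tab)
  })
  names(out) <- vapply(objectives, function(o) o$name, character(1))
  out
}

#' Write a structural-flux table to tab-separated text
#'
#' @param table a `structural_flux_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structural_fluxes <- function(table, path) {
  df <- as.data.frame(table)
  df$objective <- attr(table, "objective")
  df$scenario <- attr(table, "scenario")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
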