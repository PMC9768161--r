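# Measured organ exchange fluxes.
#
# Per-animal arteriovenous balance: the net exchange flux of a metabolite
# across the organ is the venous-minus-arterial plasma concentration
# difference times the plasma flow, normalized per 100 g body weight.
# Positive values are release into the circulation, negative values uptake.
# Plasma flow is derived from PAH indicator dilution (Fick's principle):
# urinary PAH excretion rate divided by the arteriovenous PAH difference.
# Total ammoniagenesis is the renal (venous) ammonia flux plus urinary
# ammonia excretion.

#' Renal plasma flow from PAH indicator dilution
#'
#' Fick's principle applied to an infused tracer: everything extracted from
#' plasma appears in urine at steady state, so plasma flow equals the urinary
#' PAH excretion rate divided by the arteriovenous concentration difference.
#'
#' @param urinary_pah_rate urinary PAH excretion rate, nmol min^-1.
#' @param arterial_pah,venous_pah plasma PAH concentrations, nmol ml^-1;
#'   arterial must exceed venous (net extraction).
#' @return plasma flow in ml min^-1.
#' @export
renal_plasma_flow_pah <- function(urinary_pah_rate, arterial_pah, venous_pah) {
  if (any(arterial_pah <= venous_pah))
    stop("no PAH extraction: arterial concentration must exceed venous",
         call. = FALSE)
  urinary_pah_rate / (arterial_pah - venous_pah)
}

#' Arteriovenous exchange flux of a metabolite
#'
#' Release-positive sign convention: positive values are substrate release by
#' the organ, negative values substrate uptake.  Normalized per 100 g body
#' weight; with bilateral renal measurements the value covers both kidneys.
#'
#' @param arterial,venous plasma concentrations, nmol ml^-1.
#' @param plasma_flow plasma flow, ml min^-1 (>= 0).
#' @param body_weight body weight in g (> 0).
#' @return exchange flux in nmol (100 g bw)^-1 min^-1.
#' @export
exchange_flux <- function(arterial, venous, plasma_flow, body_weight) {
  if (any(plasma_flow < 0))
    stop("plasma flow must be >= 0", call. = FALSE)
  if (any(body_weight <= 0))
    stop("body weight must be > 0", call. = FALSE)
  (venous - arterial) * plasma_flow * 100 / body_weight
}

#' Urinary excretion rate
#'
#' @param urine_conc urine concentration, nmol ml^-1 (>= 0).
#' @param urine_flow urine flow, ml min^-1 (>= 0).
#' @param body_weight body weight in g (> 0).
#' @return excretion rate in nmol (100 g bw)^-1 min^-1.
#' @export
urinary_excretion <- function(urine_conc, urine_flow, body_weight) {
  if (any(urine_conc < 0) || any(urine_flow < 0))
    stop("urine concentration and flow must be >= 0", call. = FALSE)
  if (any(body_weight <= 0))
    stop("body weight must be > 0", call. = FALSE)
  urine_conc * urine_flow * 100 / body_weight
}

#' Total ammoniagenesis
#'
#' Renal venous ammonia flux plus urinary ammonia excretion, with the urinary
#' fraction as a percentage of the total (undefined when the total is not
#' positive).
#'
#' @param renal_flux venous ammonia exchange flux, nmol (100 g bw)^-1 min^-1
#'   (release-positive).
#' @param urinary_rate urinary ammonia excretion, same units (>= 0).
#' @return list with `total` and `percent_urinary` (`NA` when total <= 0).
#' @export
total_ammoniagenesis <- function(renal_flux, urinary_rate) {
  if (any(urinary_rate < 0))
    stop("urinary excretion rate must be >= 0", call. = FALSE)
  total <- renal_flux + urinary_rate
  pct <- ifelse(total > 0, 100 * urinary_rate / total, NA_real_)
  list(total = total, percent_urinary = pct)
}

#' Read a per-animal measurement table
#'
#' Tab-separated, one row per (animal, metabolite), with columns `animal`,
#' `group`, `metabolite`, `bw_g`, `art_conc`, `ven_conc`, `urine_conc`,
#' `urine_flow`, `plasma_flow`, `hematocrit`.  Concentrations are plasma
#' values in nmol ml^-1, flows in ml min^-1, body weight in g.  Hematocrit is
#' carried for completeness but enters no default computation (plasma flow
#' and plasma concentrations are used throughout).
#'
#' @param path path to the TSV file.
#' @return validated data.frame.
#' @export
read_animal_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("animal", "group", "metabolite", "bw_g", "art_conc",
                "ven_conc", "urine_conc", "urine_flow", "plasma_flow",
                "hematocrit")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("animal table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(df$bw_g <= 0))
    stop("body weight must be > 0", call. = FALSE)
  if (any(df$plasma_flow < 0) || any(df$urine_flow < 0))
    stop("flows must be >= 0", call. = FALSE)
  if (any(df$hematocrit < 0 | df$hematocrit >= 1))
    stop("hematocrit must lie in [0, 1)", call. = FALSE)
  df
}

#' Compute measured exchange fluxes from per-animal measurements
#'
#' Applies [exchange_flux()] to every (animal, metabolite) row and, for the
#' designated ammonia metabolite, also computes urinary excretion, total
#' ammoniagenesis and the urinary percentage per animal.
#'
#' @param animals data.frame in [read_animal_table()] layout.
#' @param ammonia_metabolite name of the ammonia row used for the
#'   ammoniagenesis summary (default `"ammonia"`; skipped when absent).
#' @return list with `fluxes` (data.frame: animal, group, metabolite, flux)
#'   and `ammonia` (data.frame: animal, group, renal_flux, urinary_rate,
#'   total, percent_urinary; zero rows when the metabolite is absent).
#' @export
compute_measured_fluxes <- function(animals, ammonia_metabolite = "ammonia") {
  flux <- exchange_flux(animals$art_conc, animals$ven_conc,
                        animals$plasma_flow, animals$bw_g)
  fluxes <- data.frame(animal = animals$animal, group = animals$group,
                       metabolite = animals$metabolite, flux = flux,
                       stringsAsFactors = FALSE)
  amm <- animals[animals$metabolite == ammonia_metabolite, , drop = FALSE]
  if (nrow(amm)) {
    renal <- exchange_flux(amm$art_conc, amm$ven_conc, amm$plasma_flow,
                           amm$bw_g)
    urin <- urinary_excretion(amm$urine_conc, amm$urine_flow, amm$bw_g)
    tot <- total_ammoniagenesis(renal, urin)
    ammonia <- data.frame(animal = amm$animal, group = amm$group,
                          renal_flux = renal, urinary_rate = urin,
                          total = tot$total,
                          percent_urinary = tot$percent_urinary,
                          stringsAsFactors = FALSE)
  } else {
    ammonia <- data.frame(animal = character(0), group = character(0),
                          renal_flux = numeric(0), urinary_rate = numeric(0),
                          total = numeric(0), percent_urinary = numeric(0),
                          stringsAsFactors = FALSE)
  }
  list(fluxes = fluxes, ammonia = ammonia)
}

#' Group-level flux summaries
#'
#' Per group and metabolite: mean, SEM, median and range.  With exactly two
#' groups, a nonparametric two-group comparison (Wilcoxon rank-sum, exact
#' where possible) per metabolite, and a combined P across metabolites by
#' Stouffer's method with direction taken from the sign of the group mean
#' difference.
#'
#' @param fluxes data.frame with columns `animal`, `group`, `metabolite`,
#'   `flux` (as from [compute_measured_fluxes()]).
#' @return list with `summary` (per group x metabolite statistics), `tests`
#'   (per-metabolite two-group P; zero rows unless exactly two groups) and
#'   `combined_p` (`NA` unless two groups and >= 1 usable test).
#' @export
group_summary <- function(fluxes) {
  stopifnot(all(c("group", "metabolite", "flux") %in% names(fluxes)))
  groups <- sort(unique(fluxes$group))
  cells <- expand.grid(group = groups,
                       metabolite = sort(unique(fluxes$metabolite)),
                       stringsAsFactors = FALSE)
  stats_rows <- lapply(seq_len(nrow(cells)), function(i) {
    x <- fluxes$flux[fluxes$group == cells$group[i] &
                       fluxes$metabolite == cells$metabolite[i]]
    data.frame(group = cells$group[i], metabolite = cells$metabolite[i],
               n = length(x), mean = mean(x),
               sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0,
               median = stats::median(x), min = min(x), max = max(x),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, stats_rows)

  tests <- data.frame(metabolite = character(0), p = numeric(0),
                      direction = numeric(0), stringsAsFactors = FALSE)
  combined_p <- NA_real_
  if (length(groups) == 2L) {
    mets <- sort(unique(fluxes$metabolite))
    rows <- lapply(mets, function(m) {
      x <- fluxes$flux[fluxes$group == groups[1] & fluxes$metabolite == m]
      y <- fluxes$flux[fluxes$group == groups[2] & fluxes$metabolite == m]
      if (length(x) == 0L || length(y) == 0L)
        return(NULL)
      p <- suppressWarnings(stats::wilcox.test(y, x)$p.value)
      data.frame(metabolite = m, p = p,
                 direction = sign(mean(y) - mean(x)),
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      tests <- do.call(rbind, rows)
      usable <- !is.na(tests$p) & tests$direction != 0
      if (any(usable))
        combined_p <- stouffer_combined_p(tests$p[usable] / 2,
                                          tests$direction[usable])
    }
  }
  list(summary = summary, tests = tests, combined_p = combined_p)
}
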