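# Expression-constrained predictions.
#
# Under a perturbed condition the active pathway set is restricted: only the
# elementary modes that contain at least one reaction associated with a
# significantly upregulated gene are assumed active, one gene scenario at a
# time, and structural fluxes are recomputed on each restricted set.

#' Read a differential-expression table
#'
#' Tab-separated text with header `gene<TAB>log2fc<TAB>padj` (log2 fold
#' changes and multiplicity-adjusted P values, as produced by a standard
#' differential-expression pipeline).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene`, `log2fc`, `padj`.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "log2fc", "padj") %in% names(df)))
    stop("expression table must have header 'gene<TAB>log2fc<TAB>padj'",
         call. = FALSE)
  if (anyDuplicated(df$gene))
    stop("gene symbols must be unique in the expression table", call. = FALSE)
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE))
    stop("adjusted P values must lie in [0, 1]", call. = FALSE)
  df
}

#' Select significantly upregulated genes
#'
#' Upregulated means positive log2 fold change with adjusted P below the
#' significance threshold.  The result is deterministically ordered
#' (alphabetical).
#'
#' @param expr data.frame with columns `gene`, `log2fc`, `padj`.
#' @param alpha significance threshold on the adjusted P value (default 0.05).
#' @return character vector of gene symbols (possibly empty).
#' @export
select_upregulated <- function(expr, alpha = 0.05) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(expr)))
  hits <- expr$gene[!is.na(expr$log2fc) & !is.na(expr$padj) &
                      expr$log2fc > 0 & expr$padj < alpha]
  sort(as.character(hits))
}

# Reactions carrying a gene, case-insensitive on symbols.
.reactions_for_gene <- function(model, gene) {
  if (length(model$gene_map) == 0L)
    stop("model has no gene map; attach one with set_gene_map()", call. = FALSE)
  hits <- vapply(model$gene_map, function(gs)
    any(toupper(gs) == toupper(gene)), logical(1))
  names(model$gene_map)[hits]
}

#' Restrict a mode set to modes touching a gene's reactions
#'
#' Keeps exactly the modes whose support intersects the set of reactions
#' mapped to the gene (case-insensitive symbol match); canonical mode order
#' is preserved.
#'
#' @param modes a `mode_set`.
#' @param model a `metabolic_model` with a gene map.
#' @param gene a gene symbol.
#' @return the restricted `mode_set` (possibly empty).
#' @export
restrict_modes <- function(modes, model, gene) {
  stopifnot(inherits(modes, "mode_set"))
  rxns <- .reactions_for_gene(model, gene)
  if (length(rxns) == 0L)
    stop("unmapped gene: '", gene,
         "' is associated with no reaction in the model", call. = FALSE)
  cols <- match(rxns, modes$reaction_ids)
  keep <- rowSums(modes$coeff[, cols, drop = FALSE] != 0) > 0
  .new_mode_set(modes$coeff[keep, , drop = FALSE], modes$reaction_ids)
}

#' Per-gene structural-flux scenarios
#'
#' For each upregulated gene, restricts the mode set to the pathways
#' containing that gene and recomputes structural fluxes under the fixed
#' objective.  Scenarios whose restricted set is empty or cannot reach the
#' objective are flagged, never dropped.
#'
#' @param modes the full `mode_set`.
#' @param model a `metabolic_model` with a gene map.
#' @param objective an [objective_spec()].
#' @param genes nonempty character vector of gene symbols.
#' @return named list of scenarios: `list(gene, n_modes, reachable, flag,
#'   table)`; `table` is `NULL` when flagged.
#' @export
per_gene_predictions <- function(modes, model, objective, genes) {
  if (length(genes) == 0L)
    stop("'genes' must be nonempty", call. = FALSE)
  out <- lapply(genes, function(g) {
    restricted <- restrict_modes(modes, model, g)
    if (n_modes(restricted) == 0L)
      return(list(gene = g, n_modes = 0L, reachable = FALSE,
                  flag = "empty restricted set", table = NULL))
    tab <- tryCatch(
      structural_fluxes(restricted, model, objective,
                        scenario = paste0("gene:", g)),
      error = function(e) {
        if (grepl("objective unreachable", conditionMessage(e))) NULL
        else stop(e)
      })
    list(gene = g, n_modes = n_modes(restricted),
         reachable = !is.null(tab),
         flag = if (is.null(tab)) "objective unreachable" else "",
         table = tab)
  })
  names(out) <- genes
  out
}

#' Relative change between two structural-flux tables
#'
#' Percent change of the normalized structural flux of every reaction in a
#' constrained prediction relative to a baseline prediction under the same
#' model and objective.  Reactions with zero baseline and zero constrained
#' flux change by 0%; reactions with zero baseline but positive constrained
#' flux are flagged as `new flux` (no finite percentage exists).
#'
#' @param constrained,baseline `structural_flux_table` objects over the same
#'   reactions and objective.
#' @return data.frame with columns `reaction`, `pct_change` (`NA` for new
#'   fluxes) and `flag`.
#' @export
relative_change <- function(constrained, baseline) {
  if (!identical(constrained$reaction, baseline$reaction))
    stop("tables cover different reaction sets", call. = FALSE)
  if (!identical(attr(constrained, "objective"), attr(baseline, "objective")))
    stop("tables were computed under different objectives", call. = FALSE)
  b <- baseline$aStruF
  k <- constrained$aStruF
  pct <- 100 * (k - b) / b
  flag <- rep("", length(b))
  both_zero <- b == 0 & k == 0
  pct[both_zero] <- 0
  new_flux <- b == 0 & k > 0
  pct[new_flux] <- NA_real_
  flag[new_flux] <- "new flux"
  data.frame(reaction = constrained$reaction, pct_change = pct, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}
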