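#' Construct a stoichiometric metabolic model
#'
#' The central container consumed by every other function in the package: an
#' exact stoichiometric matrix over declared reactions and metabolites, a
#' reversibility flag per reaction, an internal/external split per metabolite,
#' and three optional annotation layers — substrate uptake reactions with
#' their molecular weights (needed to normalize mode yields across substrates
#' of very different size, e.g. glucose vs. whole protein), a gene map linking
#' reactions to gene symbols, and an exchange map linking model exchange
#' reactions to the metabolite names used in measured flux tables.
#'
#' Coefficients are stored as exact rationals (numerator and denominator
#' matrices); decimal input is expanded by powers of ten.  Elementary-mode
#' enumeration depends on exact support tests, so no float round-off is
#' allowed into the stoichiometry.
#'
#' @param reaction_ids character vector of unique reaction identifiers.
#' @param reversible logical vector, one flag per reaction.
#' @param metabolite_ids character vector of unique metabolite identifiers.
#' @param is_internal logical vector, one flag per metabolite; internal
#'   metabolites are balanced at steady state, external ones are not.
#' @param stoich_num,stoich_den integer-valued numerator/denominator matrices
#'   (metabolites x reactions); negative entries consume, positive produce.
#' @param substrates named numeric: uptake-exchange reaction id -> molecular
#'   weight (g/mol, > 0).
#' @param gene_map named list: reaction id -> character vector of gene symbols.
#' @param exchange_map named character: exchange reaction id -> measured
#'   metabolite name.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(reaction_ids, reversible, metabolite_ids,
                            is_internal, stoich_num, stoich_den = NULL,
                            substrates = numeric(0), gene_map = list(),
                            exchange_map = character(0)) {
  reaction_ids <- as.character(reaction_ids)
  metabolite_ids <- as.character(metabolite_ids)
  nr <- length(reaction_ids); nm <- length(metabolite_ids)
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction id: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite id: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(reversible) != nr)
    stop("'reversible' must have one flag per reaction", call. = FALSE)
  if (length(is_internal) != nm)
    stop("'is_internal' must have one flag per metabolite", call. = FALSE)
  if (is.null(stoich_num)) stoich_num <- matrix(0, nm, nr)
  stoich_num <- as.matrix(stoich_num)
  if (is.null(stoich_den)) stoich_den <- matrix(1, nrow(stoich_num), ncol(stoich_num))
  stoich_den <- as.matrix(stoich_den)
  if (!identical(dim(stoich_num), c(nm, nr)) ||
      !identical(dim(stoich_den), c(nm, nr)))
    stop("stoichiometric matrix must be (#metabolites) x (#reactions)",
         call. = FALSE)
  if (any(stoich_den <= 0))
    stop("stoichiometric denominators must be positive", call. = FALSE)
  dimnames(stoich_num) <- dimnames(stoich_den) <-
    list(metabolite_ids, reaction_ids)
  if (length(substrates)) {
    if (is.null(names(substrates)) || any(!nzchar(names(substrates))))
      stop("'substrates' must be a named numeric vector", call. = FALSE)
    bad <- setdiff(names(substrates), reaction_ids)
    if (length(bad))
      stop("substrate reaction not declared in the model: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(!is.finite(substrates) | substrates <= 0))
      stop("all substrate molecular weights must be > 0", call. = FALSE)
    ext <- !is_internal
    for (rid in names(substrates)) {
      col <- stoich_num[, rid]
      if (!any(ext & col != 0))
        stop("substrate reaction '", rid,
             "' involves no external metabolite", call. = FALSE)
    }
  }
  if (length(gene_map)) {
    bad <- setdiff(names(gene_map), reaction_ids)
    if (length(bad))
      stop("gene map references undeclared reaction: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(exchange_map)) {
    bad <- setdiff(names(exchange_map), reaction_ids)
    if (length(bad))
      stop("exchange map references undeclared reaction: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(
    reaction_ids = reaction_ids,
    reversible = as.logical(reversible),
    metabolite_ids = metabolite_ids,
    is_internal = as.logical(is_internal),
    stoich_num = stoich_num,
    stoich_den = stoich_den,
    substrates = substrates,
    gene_map = gene_map,
    exchange_map = exchange_map
  ), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("Metabolic model: %d reactions (%d reversible), %d metabolites (%d internal, %d external)\n",
              length(x$reaction_ids), sum(x$reversible),
              length(x$metabolite_ids), sum(x$is_internal),
              sum(!x$is_internal)))
  if (length(x$substrates))
    cat(sprintf("  substrates: %s\n",
                paste(names(x$substrates), collapse = ", ")))
  if (length(x$exchange_map))
    cat(sprintf("  exchange map: %d reactions\n", length(x$exchange_map)))
  invisible(x)
}

#' Extract the stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @param internal_only keep only rows of internal (balanced) metabolites.
#' @param exact return `list(num, den)` instead of a numeric matrix.
#' @return numeric matrix (metabolites x reactions), or exact num/den pair.
#' @export
stoich_matrix <- function(model, internal_only = FALSE, exact = FALSE) {
  keep <- if (internal_only) model$is_internal else rep(TRUE, length(model$metabolite_ids))
  num <- model$stoich_num[keep, , drop = FALSE]
  den <- model$stoich_den[keep, , drop = FALSE]
  if (exact) list(num = num, den = den) else num / den
}

# Integer internal stoichiometric matrix: each metabolite row scaled by the
# lcm of its denominators (row scaling does not change the nullspace).
.internal_int_matrix <- function(model) {
  ex <- stoich_matrix(model, internal_only = TRUE, exact = TRUE)
  M <- ex$num
  for (i in seq_len(nrow(M))) {
    L <- .lcm_vec(ex$den[i, ])
    if (L != 1) {
      M[i, ] <- ex$num[i, ] * (L / ex$den[i, ])
      .check_exact(M[i, ], "stoichiometry scaling")
    }
  }
  M
}

.METATOOL_SECTIONS <- c("-ENZREV", "-ENZIRREV", "-METINT", "-METEXT", "-CAT")

#' Parse a METATOOL-format model document
#'
#' Reads the five-section METATOOL text dialect: `-ENZREV` (reversible
#' reactions), `-ENZIRREV` (irreversible reactions), `-METINT` (internal
#' metabolites), `-METEXT` (external metabolites) and `-CAT` (catalysed
#' reactions, one per line in `id : lhs = rhs` form).  Sections may appear in
#' any order; blank lines, trailing whitespace and `#` comment lines are
#' ignored.  Coefficients may be integers, fractions (`3/2`) or decimals
#' (expanded exactly by powers of ten); both `2 A` and `2A` spellings are
#' accepted.  Left-hand-side coefficients are stored negative (consumption),
#' right-hand-side positive (production).
#'
#' @param text the document, as a single string or a character vector of lines.
#' @return a [metabolic_model()] (without substrate/gene/exchange annotations,
#'   which METATOOL cannot carry; see [apply_sidecar()] and [read_gene_map()]).
#' @seealso [read_metatool()], [write_metatool()]
#' @export
parse_metatool <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", text)
  lines <- trimws(lines)

  section <- NA_character_
  body <- stats::setNames(vector("list", length(.METATOOL_SECTIONS)),
                          .METATOOL_SECTIONS)
  seen <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (toupper(ln) %in% .METATOOL_SECTIONS) {
      section <- toupper(ln)
      seen <- union(seen, section)
      next
    }
    if (is.na(section))
      stop("METATOOL parse error at line ", i,
           ": content before any section header", call. = FALSE)
    body[[section]] <- c(body[[section]], stats::setNames(list(ln), i))
  }
  missing <- setdiff(.METATOOL_SECTIONS, seen)
  if (length(missing))
    stop("METATOOL parse error: missing section header(s) ",
         paste(missing, collapse = ", "), call. = FALSE)

  split_ids <- function(entries) {
    if (length(entries) == 0L) return(character(0))
    unlist(strsplit(unlist(entries, use.names = FALSE), "[ \t]+"))
  }
  rev_ids <- split_ids(body[["-ENZREV"]])
  irrev_ids <- split_ids(body[["-ENZIRREV"]])
  int_ids <- split_ids(body[["-METINT"]])
  ext_ids <- split_ids(body[["-METEXT"]])

  reaction_ids <- c(rev_ids, irrev_ids)
  dup <- reaction_ids[duplicated(reaction_ids)]
  if (length(dup))
    stop("METATOOL parse error: duplicate reaction id ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  metabolite_ids <- c(int_ids, ext_ids)
  dupm <- metabolite_ids[duplicated(metabolite_ids)]
  if (length(dupm))
    stop("METATOOL parse error: duplicate metabolite id ",
         paste(unique(dupm), collapse = ", "), call. = FALSE)

  nm <- length(metabolite_ids); nr <- length(reaction_ids)
  num <- matrix(0, nm, nr, dimnames = list(metabolite_ids, reaction_ids))
  den <- matrix(1, nm, nr, dimnames = list(metabolite_ids, reaction_ids))
  cat_seen <- character(0)

  for (j in seq_along(body[["-CAT"]])) {
    ln <- body[["-CAT"]][[j]]
    lineno <- names(body[["-CAT"]])[j]
    ln <- sub("\\.\\s*$", "", ln)  # optional trailing period
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("METATOOL parse error at line ", lineno,
           ": expected 'id : lhs = rhs' in CAT entry '", ln, "'", call. = FALSE)
    rid <- trimws(parts[1])
    if (!(rid %in% reaction_ids))
      stop("METATOOL parse error at line ", lineno, ": reaction '", rid,
           "' in CAT was not declared in ENZREV/ENZIRREV", call. = FALSE)
    if (rid %in% cat_seen)
      stop("METATOOL parse error at line ", lineno,
           ": duplicate CAT entry for reaction '", rid, "'", call. = FALSE)
    cat_seen <- c(cat_seen, rid)
    sides <- strsplit(parts[2], "=", fixed = TRUE)[[1]]
    if (length(sides) > 2L)
      stop("METATOOL parse error at line ", lineno,
           ": more than one '=' in CAT entry", call. = FALSE)
    if (length(sides) == 1L) sides <- c(sides, "")
    for (side in 1:2) {
      sgn <- if (side == 1L) -1 else 1
      terms <- strsplit(sides[side], "+", fixed = TRUE)[[1]]
      for (term in terms) {
        term <- trimws(term)
        if (!nzchar(term)) next
        parsed <- .parse_term(term, lineno)
        met <- parsed$met
        if (!(met %in% metabolite_ids))
          stop("METATOOL parse error at line ", lineno, ": metabolite '",
               met, "' was not declared in METINT/METEXT", call. = FALSE)
        # accumulate exactly: a/b + c/d
        n0 <- num[met, rid]; d0 <- den[met, rid]
        n1 <- sgn * parsed$num; d1 <- parsed$den
        nn <- n0 * d1 + n1 * d0
        dd <- d0 * d1
        .check_exact(c(nn, dd), "stoichiometry accumulation")
        g <- .gcd2(nn, dd)
        if (g > 1) { nn <- nn / g; dd <- dd / g }
        if (nn == 0) dd <- 1
        num[met, rid] <- nn
        den[met, rid] <- dd
      }
    }
  }

  metabolic_model(
    reaction_ids = reaction_ids,
    reversible = c(rep(TRUE, length(rev_ids)), rep(FALSE, length(irrev_ids))),
    metabolite_ids = metabolite_ids,
    is_internal = c(rep(TRUE, length(int_ids)), rep(FALSE, length(ext_ids))),
    stoich_num = num, stoich_den = den
  )
}

# Parse one reaction term: "A", "2 A", "2A", "3/2 A", "0.5A".
.parse_term <- function(term, lineno) {
  tokens <- strsplit(term, "[ \t]+")[[1]]
  if (length(tokens) == 2L) {
    coef <- .parse_coef(tokens[1])
    met <- tokens[2]
  } else if (length(tokens) == 1L) {
    m <- regmatches(term, regexec("^([0-9]+(?:\\.[0-9]+)?|[0-9]+/[0-9]+)([A-Za-z_].*)$", term))[[1]]
    if (length(m) == 3L) {
      coef <- .parse_coef(m[2])
      met <- m[3]
    } else if (grepl("^[0-9.]+$", term) || grepl("^[0-9]+/[0-9]+$", term)) {
      stop("METATOOL parse error at line ", lineno,
           ": coefficient '", term, "' with no metabolite", call. = FALSE)
    } else {
      coef <- c(1, 1)
      met <- term
    }
  } else {
    stop("METATOOL parse error at line ", lineno,
         ": cannot parse term '", term, "'", call. = FALSE)
  }
  list(num = coef[1], den = coef[2], met = met)
}

#' Read a METATOOL model file
#'
#' @param path path to a METATOOL `.dat` text file.
#' @return a [metabolic_model()].
#' @export
read_metatool <- function(path) {
  parse_metatool(readLines(path, warn = FALSE))
}

#' Serialize a model to METATOOL format
#'
#' Writes the canonical dialect (one CAT line per reaction, `2 A` coefficient
#' spelling, fractions as `3/2`).  `parse_metatool(write_metatool(m))`
#' reproduces `m` field by field.
#'
#' @param model a valid [metabolic_model()].
#' @param path optional file path; when given, the text is also written there.
#' @return the document as a character vector of lines, invisibly when `path`
#'   is given.
#' @export
write_metatool <- function(model, path = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  fmt_side <- function(rid, sgn) {
    col_n <- model$stoich_num[, rid]
    col_d <- model$stoich_den[, rid]
    pick <- if (sgn < 0) col_n < 0 else col_n > 0
    mets <- model$metabolite_ids[pick]
    if (!length(mets)) return("")
    coefs <- .format_rat(abs(col_n[pick]), col_d[pick])
    terms <- ifelse(coefs == "1", mets, paste(coefs, mets))
    paste(terms, collapse = " + ")
  }
  cat_lines <- vapply(model$reaction_ids, function(rid) {
    sprintf("%s : %s = %s", rid, fmt_side(rid, -1), fmt_side(rid, +1))
  }, character(1))
  out <- c(
    "-ENZREV",
    paste(model$reaction_ids[model$reversible], collapse = " "),
    "",
    "-ENZIRREV",
    paste(model$reaction_ids[!model$reversible], collapse = " "),
    "",
    "-METINT",
    paste(model$metabolite_ids[model$is_internal], collapse = " "),
    "",
    "-METEXT",
    paste(model$metabolite_ids[!model$is_internal], collapse = " "),
    "",
    "-CAT",
    cat_lines
  )
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Structural validation report for a model
#'
#' Flags (i) dead-end internal metabolites, i.e. internal metabolites touched
#' by fewer than two reactions, which can never be balanced by a nontrivial
#' steady-state flux; (ii) reactions with all-zero stoichiometry; and (iii)
#' substrate uptake reactions that consume no external metabolite, so their
#' declared molecular weight could never enter a yield denominator.
#'
#' @param model a `metabolic_model`.
#' @return a data.frame with columns `type`, `item`, `message`; zero rows iff
#'   no issue was found.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  issues <- list()
  add <- function(type, item, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      type = type, item = item, message = message, stringsAsFactors = FALSE)

  nonzero <- model$stoich_num != 0
  for (i in which(model$is_internal)) {
    k <- sum(nonzero[i, ])
    if (k < 2L)
      add("dead_end_metabolite", model$metabolite_ids[i],
          sprintf("internal metabolite appears in %d reaction(s); cannot be balanced", k))
  }
  for (j in seq_along(model$reaction_ids)) {
    if (!any(nonzero[, j]))
      add("empty_reaction", model$reaction_ids[j],
          "reaction has all-zero stoichiometry")
  }
  ext <- !model$is_internal
  for (rid in names(model$substrates)) {
    col <- model$stoich_num[, rid]
    if (!any(ext & col < 0))
      add("substrate_not_uptake", rid,
          "substrate reaction consumes no external metabolite")
  }
  if (length(issues) == 0L)
    return(data.frame(type = character(0), item = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Split reversible reactions into irreversible pairs
#'
#' Standard preprocessing for elementary-mode enumeration: every reversible
#' reaction `R` becomes a forward copy `R` and a backward copy `R__rev` with
#' negated stoichiometry, yielding an all-irreversible model.
#'
#' @param model a `metabolic_model`.
#' @return list with `model` (the expanded irreversible model), `forward` and
#'   `backward` (integer indices into the expanded reaction list, per original
#'   reaction; `backward` is `NA` for irreversible reactions).
#' @seealso [recombine_fluxes()]
#' @export
split_reversible <- function(model) {
  nr <- length(model$reaction_ids)
  fwd <- seq_len(nr)
  bwd <- rep(NA_integer_, nr)
  ids <- model$reaction_ids
  num <- model$stoich_num
  den <- model$stoich_den
  for (j in which(model$reversible)) {
    ids <- c(ids, paste0(model$reaction_ids[j], "__rev"))
    num <- cbind(num, -model$stoich_num[, j])
    den <- cbind(den, model$stoich_den[, j])
    bwd[j] <- length(ids)
  }
  expanded <- metabolic_model(
    reaction_ids = ids,
    reversible = rep(FALSE, length(ids)),
    metabolite_ids = model$metabolite_ids,
    is_internal = model$is_internal,
    stoich_num = num, stoich_den = den
  )
  list(model = expanded, forward = fwd, backward = bwd)
}

#' Recombine an expanded flux vector into the original signed space
#'
#' @param v nonnegative flux vector over the expanded (split) reactions.
#' @param split the mapping returned by [split_reversible()].
#' @return signed flux vector over the original reactions.
#' @export
recombine_fluxes <- function(v, split) {
  fwd <- v[split$forward]
  idx <- ifelse(is.na(split$backward), 1L, split$backward)
  bwd <- v[idx]
  bwd[is.na(split$backward)] <- 0
  if (any(fwd != 0 & bwd != 0))
    stop("flux vector uses both directions of the same reversible reaction",
         call. = FALSE)
  out <- fwd - bwd
  names(out) <- split$model$reaction_ids[split$forward]
  out
}

#' Read a sidecar annotation file
#'
#' METATOOL text cannot carry substrate molecular weights or the mapping from
#' exchange reactions to measured-metabolite names, so these travel in a
#' small YAML sidecar with two blocks: `substrates` (reaction id -> molecular
#' weight in g/mol) and `exchange_map` (reaction id -> metabolite name).
#'
#' @param path path to the YAML file.
#' @return list with elements `substrates` (named numeric) and `exchange_map`
#'   (named character).
#' @export
read_sidecar <- function(path) {
  raw <- yaml::read_yaml(path)
  substrates <- numeric(0)
  if (!is.null(raw$substrates))
    substrates <- unlist(raw$substrates)
  exchange_map <- character(0)
  if (!is.null(raw$exchange_map))
    exchange_map <- vapply(raw$exchange_map, as.character, character(1))
  list(substrates = substrates, exchange_map = exchange_map)
}

#' Attach sidecar annotations to a model
#'
#' @param model a `metabolic_model`.
#' @param sidecar list as returned by [read_sidecar()].
#' @return the annotated model (validated).
#' @export
apply_sidecar <- function(model, sidecar) {
  metabolic_model(
    reaction_ids = model$reaction_ids,
    reversible = model$reversible,
    metabolite_ids = model$metabolite_ids,
    is_internal = model$is_internal,
    stoich_num = model$stoich_num,
    stoich_den = model$stoich_den,
    substrates = if (!is.null(sidecar$substrates)) sidecar$substrates else model$substrates,
    gene_map = model$gene_map,
    exchange_map = if (!is.null(sidecar$exchange_map)) sidecar$exchange_map else model$exchange_map
  )
}

#' Read a reaction-to-gene map
#'
#' Two-column tab-separated text with header `reaction<TAB>gene`; many-to-many
#' (a reaction may carry several genes and a gene several reactions).
#'
#' @param path path to the TSV file.
#' @return named list: reaction id -> character vector of gene symbols.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reaction", "gene") %in% names(df)))
    stop("gene map must have header 'reaction<TAB>gene'", call. = FALSE)
  split(as.character(df$gene), factor(df$reaction, levels = unique(df$reaction)))
}

#' Attach a gene map to a model
#'
#' @param model a `metabolic_model`.
#' @param gene_map named list, reaction id -> gene symbols.
#' @return the annotated model (validated).
#' @export
set_gene_map <- function(model, gene_map) {
  metabolic_model(
    reaction_ids = model$reaction_ids,
    reversible = model$reversible,
    metabolite_ids = model$metabolite_ids,
    is_internal = model$is_internal,
    stoich_num = model$stoich_num,
    stoich_den = model$stoich_den,
    substrates = model$substrates,
    gene_map = gene_map,
    exchange_map = model$exchange_map
  )
}
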