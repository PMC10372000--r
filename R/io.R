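#' Read a metabolic model from file
#'
#' Supports SBML Level 3 with the FBC package and a compact JSON dialect.
#' The JSON schema is an object with fields `id`, `metabolites` (array of
#' ids), `reactions` (array of `{id, stoich: {met: coefficient}, lb, ub,
#' gpr}` with `gpr` a rule string, possibly empty), and optional `biomass`
#' and `atp_maintenance` reaction ids. Exchange reactions are auto-detected
#' as those whose stoichiometry touches exactly one metabolite; for them,
#' positive flux is secretion and negative flux is uptake.
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.json` vs `.xml`/`.sbml`),
#'   `"json"`, or `"sbml"`.
#' @return A [metabolic_model].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format,
         json = .read_model_json(path),
         sbml = read_sbml_model(path))
}

#' Write a metabolic model to file
#'
#' @param model A [metabolic_model].
#' @param path Output path.
#' @param format See [read_model()].
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format,
         json = .write_model_json(model, path),
         sbml = write_sbml_model(model, path))
  invisible(path)
}

.read_model_json <- function(path) {
  x <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON model '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  for (field in c("metabolites", "reactions")) {
    if (is.null(x[[field]])) {
      stop("malformed JSON model '", path, "': missing field '", field, "'",
           call. = FALSE)
    }
  }
  reactions <- lapply(x$reactions, function(r) {
    if (is.null(r$id) || is.null(r$lb) || is.null(r$ub)) {
      stop("malformed JSON model '", path,
           "': reaction entry lacks id/lb/ub", call. = FALSE)
    }
    st <- unlist(r$stoich)
    list(id = r$id, stoich = if (length(st)) st else numeric(),
         lb = r$lb, ub = r$ub,
         gpr = if (is.null(r$gpr)) NULL else r$gpr)
  })
  metabolic_model(
    model_id = if (is.null(x$id)) "model" else x$id,
    metabolites = as.character(unlist(x$metabolites)),
    reactions = reactions,
    genes = if (is.null(x$genes)) NULL else as.character(unlist(x$genes)),
    biomass = if (is.null(x$biomass)) NA_character_ else x$biomass,
    atp_maintenance = if (is.null(x$atp_maintenance)) NA_character_
      else x$atp_maintenance)
}

.write_model_json <- function(model, path) {
  reactions <- lapply(model$rxns, function(rid) {
    st <- model$S[, rid]
    st <- st[st != 0]
    list(id = rid, stoich = as.list(st),
         lb = model$lb[[rid]], ub = model$ub[[rid]],
         gpr = render_gpr(model$gpr[[rid]]))
  })
  out <- list(id = model$id,
              metabolites = as.list(model$mets),
              reactions = reactions,
              genes = as.list(model$genes))
  if (!is.na(model$biomass)) out$biomass <- model$biomass
  if (!is.na(model$atp_maintenance)) out$atp_maintenance <- model$atp_maintenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read and write gene expression matrices
#'
#' Tab-separated values; first column gene id, remaining columns one per
#' sample. Values are nonnegative, FPKM-like normalized abundances.
#'
#' @param path File path.
#' @return `read_expression`: numeric matrix (genes x samples).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column plus samples",
                          call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- as.character(df[[1]])
  if (anyDuplicated(colnames(mat))) stop("duplicated sample ids", call. = FALSE)
  if (any(mat < 0, na.rm = TRUE)) stop("negative expression values",
                                       call. = FALSE)
  mat
}

#' @rdname read_expression
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write ternary expression calls
#'
#' Same layout as the expression table, values coded 1 (expressed),
#' -1 (not expressed), 0 (unknown).
#'
#' @param path File path.
#' @return `read_calls`: integer matrix (genes x samples).
#' @export
read_calls <- function(path) {
  mat <- read_expression_codes(path)
  bad <- setdiff(unique(as.vector(mat)), c(-1L, 0L, 1L))
  if (length(bad)) stop("invalid call codes: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  mat
}

read_expression_codes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "integer"
  rownames(mat) <- as.character(df[[1]])
  mat
}

#' @rdname read_calls
#' @param calls Integer matrix with values in \{-1, 0, 1\}.
#' @export
write_calls <- function(calls, path) {
  df <- data.frame(gene = rownames(calls), calls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write drug-target tables
#'
#' Tab-separated with columns `drug_id`, `target_genes` (semicolon-separated
#' gene ids) and `is_anticancer` (0/1 annotation flag used for enrichment).
#'
#' @param path File path.
#' @return `read_drug_table`: data frame with those three columns.
#' @export
read_drug_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "target_genes", "is_anticancer")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("drug table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$is_anticancer <- as.integer(df$is_anticancer)
  df[need]
}

#' @rdname read_drug_table
#' @param drugs Drug table data frame.
#' @export
write_drug_table <- function(drugs, path) {
  utils::write.table(drugs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split the target column of a drug table into a named list
#'
#' @param drugs Drug table as returned by [read_drug_table()].
#' @return Named list: drug id -> character vector of target gene ids.
#' @export
drug_targets <- function(drugs) {
  out <- lapply(strsplit(as.character(drugs$target_genes), ";", fixed = TRUE),
                function(x) x[nzchar(x)])
  names(out) <- drugs$drug_id
  out
}

#' Read and write medium definitions
#'
#' Tab-separated with columns `metabolite` and `max_uptake`
#' (mmol/gDW/h, nonnegative). Metabolites absent from the medium cannot be
#' taken up; see [apply_medium()].
#'
#' @param path File path.
#' @return `read_medium`: named numeric vector of maximal uptake fluxes.
#' @export
read_medium <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite", "max_uptake") %in% names(df))) {
    stop("medium table needs columns 'metabolite' and 'max_uptake'",
         call. = FALSE)
  }
  med <- as.numeric(df$max_uptake)
  names(med) <- as.character(df$metabolite)
  if (any(med < 0)) stop("uptake bounds must be nonnegative", call. = FALSE)
  med
}

#' @rdname read_medium
#' @param medium Named numeric vector (metabolite -> max uptake).
#' @export
write_medium <- function(medium, path) {
  utils::write.table(
    data.frame(metabolite = names(medium), max_uptake = as.numeric(medium)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
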