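## Delimited-text readers and writers for the four trial inputs.  CSV or
## TSV is autodetected from the file extension.

.read_delim <- function(path, row_names = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, row.names = row_names,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

.write_delim <- function(x, path, row_names = FALSE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(x, path, sep = sep, row.names = row_names,
                     col.names = TRUE, quote = FALSE)
}

#' Write a trial data bundle to delimited text files
#'
#' Writes `markers.csv` (line id column + marker codes), `pedigree.csv`,
#' `phenotypes.csv`, `env_covariates.csv` and, for simulated data with
#' ground truth, `truth.json` into `dir`.
#'
#' @param data a `"met_data"` bundle.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_met_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- data.frame(line = rownames(data$markers), data$markers,
                   check.names = FALSE)
  .write_delim(mk, file.path(dir, "markers.csv"))
  .write_delim(data$pedigree, file.path(dir, "pedigree.csv"))
  .write_delim(data$pheno, file.path(dir, "phenotypes.csv"))
  ec <- data.frame(site = rownames(data$env_covariates),
                   data$env_covariates, check.names = FALSE)
  .write_delim(ec, file.path(dir, "env_covariates.csv"))
  if (!is.null(data$truth) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      lapply(data$truth, function(x) if (is.matrix(x)) as.data.frame(x) else x),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  invisible(dir)
}

#' Read and cross-validate the four trial input files
#'
#' Reads markers, pedigree, plot-level phenotypes and site covariables from
#' delimited text, validates the cross-references (every phenotyped
#' accession has a marker row; every site has a covariable row; no
#' duplicated line ids) and mean-imputes missing marker codes, reporting
#' how many were imputed.
#'
#' @param markers,pedigree,phenotypes,env_covariates file paths (CSV or
#'   TSV). `markers` and `pedigree` may be `NULL` when the downstream
#'   models do not need them.
#' @return a `"met_data"` bundle (without ground truth).
#' @export
read_met_inputs <- function(phenotypes, markers = NULL, pedigree = NULL,
                            env_covariates = NULL) {
  pheno <- .read_delim(phenotypes)
  need <- c("site", "line")
  if (!all(need %in% names(pheno))) {
    stop("phenotype file needs columns: ", paste(need, collapse = ", "))
  }
  if (!"check" %in% names(pheno)) pheno$check <- FALSE
  pheno$check <- as.logical(pheno$check)

  mk <- NULL
  if (!is.null(markers)) {
    tab <- .read_delim(markers)
    if (names(tab)[1] != "line") stop("marker file must start with a 'line' column")
    ids <- as.character(tab$line)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) stop("duplicate line ids in marker file: ",
                          paste(dup, collapse = ", "))
    mk <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mk) <- ids
    n_miss <- sum(is.na(mk))
    if (n_miss) {
      cm <- colMeans(mk, na.rm = TRUE)
      idx <- which(is.na(mk), arr.ind = TRUE)
      mk[idx] <- cm[idx[, 2]]
      message("mean-imputed ", n_miss, " missing marker codes in ",
              length(unique(idx[, 2])), " columns")
    }
    acc <- unique(as.character(pheno$line[!pheno$check]))
    unknown <- setdiff(acc, rownames(mk))
    if (length(unknown)) {
      stop("phenotyped accessions without marker rows: ",
           paste(utils::head(unknown, 10L), collapse = ", "))
    }
  }

  ped <- if (!is.null(pedigree)) .read_delim(pedigree) else NULL

  ec <- NULL
  if (!is.null(env_covariates)) {
    tab <- .read_delim(env_covariates)
    if (names(tab)[1] != "site") stop("covariable file must start with a 'site' column")
    ec <- as.matrix(tab[, -1, drop = FALSE])
    rownames(ec) <- as.character(tab$site)
    missing_sites <- setdiff(unique(as.character(pheno$site)), rownames(ec))
    if (length(missing_sites)) {
      stop("site(s) in phenotypes absent from covariables: ",
           paste(missing_sites, collapse = ", "))
    }
  }

  structure(list(pheno = pheno, markers = mk, pedigree = ped,
                 env_covariates = ec, truth = NULL, config = NULL),
            class = "met_data")
}
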