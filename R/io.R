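# Delimited-text readers and writers. TSV/CSV are autodetected by
# extension; the PLINK .raw dialect is read-only. Missing genotypes are a
# hard error — the engine requires complete data, and silent imputation
# would change cell membership.

.sepFor <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE))
  "," else "\t"

#' Read a genotype matrix
#'
#' Delimited dialect: a header row of SNP ids, a first column of subject
#' ids, and 0/1/2 minor-allele-count cells. PLINK `.raw` dialect: the
#' standard `FID IID PAT MAT SEX PHENOTYPE` leader followed by per-SNP
#' allele-dosage columns (`rsid_A`), coerced to integer 0/1/2. Any missing
#' or malformed genotype is an error naming the offending row and column.
#'
#' @param path file path (.tsv/.txt tab, .csv comma, .raw PLINK).
#' @param format `"auto"` (by extension), `"delimited"` or `"plink_raw"`.
#' @return Integer matrix, subjects x SNPs, with ids as dimnames.
#' @export
readGenotypes <- function(path, format = c("auto", "delimited",
                                           "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.raw$", path, ignore.case = TRUE)) "plink_raw"
              else "delimited"
  if (format == "plink_raw") {
    df <- utils::read.table(path, header = TRUE, sep = "",
                            na.strings = c("NA", "-9"), check.names = FALSE,
                            stringsAsFactors = FALSE)
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(lead %in% colnames(df)))
      stop("not a PLINK .raw file: missing leader columns", call. = FALSE)
    ids <- as.character(df$IID)
    g <- as.matrix(df[, setdiff(colnames(df), lead), drop = FALSE])
    colnames(g) <- sub("_[ACGT0-9]+$", "", colnames(g))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = .sepFor(path),
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    g <- as.matrix(df[, -1L, drop = FALSE])
  }
  if (anyDuplicated(ids))
    stop("duplicate subject ids in ", path, call. = FALSE)
  if (anyDuplicated(colnames(g)))
    stop("duplicate SNP ids in ", path, call. = FALSE)
  bad <- which(!(g %in% c(0, 1, 2)) | is.na(g), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid or missing genotype at subject '%s', SNP '%s'",
                 ids[bad[1L, 1L]], colnames(g)[bad[1L, 2L]]),
         call. = FALSE)
  storage.mode(g) <- "integer"
  rownames(g) <- ids
  g
}

#' Write a genotype matrix
#'
#' Inverse of the delimited [readGenotypes()] dialect.
#'
#' @param geno integer matrix, subjects x SNPs, with dimnames.
#' @param path output path (.csv writes comma-separated, else tab).
#' @export
writeGenotypes <- function(geno, path) {
  df <- data.frame(subject_id = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .sepFor(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a survival phenotype table
#'
#' Reads a delimited table with subject id, follow-up time, event status
#' and optional covariate columns, validating types and ranges.
#'
#' @param path file path.
#' @param timeCol,statusCol,subjectCol column names.
#' @param covariateCols character vector of covariate column names
#'   (default: none).
#' @return data.frame with columns subject_id, time, status and any
#'   covariates, in file order.
#' @export
readPhenotype <- function(path, timeCol = "time", statusCol = "status",
                          covariateCols = NULL,
                          subjectCol = "subject_id") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .sepFor(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(subjectCol, timeCol, statusCol, covariateCols)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(subject_id = as.character(df[[subjectCol]]),
                    time = as.numeric(df[[timeCol]]),
                    status = df[[statusCol]], stringsAsFactors = FALSE)
  if (anyDuplicated(out$subject_id))
    stop("duplicate subject ids in ", path, call. = FALSE)
  bad <- which(!is.finite(out$time) | out$time < 0)
  if (length(bad))
    stop(sprintf("invalid time for subject '%s' (row %d)",
                 out$subject_id[bad[1L]], bad[1L]), call. = FALSE)
  bad <- which(!(out$status %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("status must be 0/1; subject '%s' (row %d)",
                 out$subject_id[bad[1L]], bad[1L]), call. = FALSE)
  out$status <- as.integer(out$status)
  for (cc in covariateCols) out[[cc]] <- as.numeric(df[[cc]])
  out
}

#' Assemble an MdrSurvData from genotype and phenotype files
#'
#' Reads both files and aligns phenotype rows to genotype subject order by
#' id; every genotype subject must have exactly one phenotype row.
#'
#' @param genoPath,phenoPath file paths.
#' @param format genotype file format, see [readGenotypes()].
#' @param ... passed to [readPhenotype()] (column names).
#' @return An [MdrSurvData-class].
#' @export
readDataset <- function(genoPath, phenoPath, format = "auto", ...) {
  g <- readGenotypes(genoPath, format)
  ph <- readPhenotype(phenoPath, ...)
  idx <- match(rownames(g), ph$subject_id)
  if (anyNA(idx))
    stop("phenotype rows missing for subject(s): ",
         paste(utils::head(rownames(g)[is.na(idx)], 3L), collapse = ", "),
         call. = FALSE)
  ph <- ph[idx, , drop = FALSE]
  covCols <- setdiff(colnames(ph), c("subject_id", "time", "status"))
  MdrSurvData(g, ph$time, ph$status,
              covariates = if (length(covCols))
                ph[, covCols, drop = FALSE])
}

#' Write a simulated dataset to delimited files
#'
#' Emits `<prefix>_genotypes.tsv`, `<prefix>_phenotype.tsv` and a
#' `<prefix>_meta.json` sidecar carrying the simulation configuration,
#' truth record and seeds, so a dataset is fully reproducible and
#' re-loadable with [readDataset()].
#'
#' @param sim result of [buildDataset()], or an [MdrSurvData-class].
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths.
#' @export
writeDataset <- function(sim, prefix) {
  data <- if (is(sim, "MdrSurvData")) sim else sim$data
  truth <- if (is(sim, "MdrSurvData")) NULL else sim$truth
  gPath <- paste0(prefix, "_genotypes.tsv")
  pPath <- paste0(prefix, "_phenotype.tsv")
  mPath <- paste0(prefix, "_meta.json")
  writeGenotypes(genotypes(data), gPath)
  ph <- data.frame(subject_id = colnames(data), time = survTime(data),
                   status = survStatus(data), stringsAsFactors = FALSE)
  cv <- covariateMatrix(data)
  if (!is.null(cv)) ph <- cbind(ph, as.data.frame(cv))
  utils::write.table(ph, pPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(n = ncol(data), p = nrow(data))
  if (!is.null(truth)) {
    cfg <- unclass(truth$config)
    cfg$penetrance <- if (!is.null(cfg$penetrance))
      list(f = cfg$penetrance@f, maf = cfg$penetrance@maf,
           h2 = cfg$penetrance@h2, K = cfg$penetrance@K)
    meta$truth <- list(causalPair = truth$causalPair,
                       censorBound = truth$censorBound,
                       censoredFraction = truth$censoredFraction)
    meta$config <- cfg
  }
  jsonlite::write_json(meta, mPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(genotypes = gPath, phenotype = pPath, meta = mPath))
}
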