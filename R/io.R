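# ---- genotype / phenotype / covariate file formats -------------------------

.check_dosages <- function(vals, lines_offset, path) {
  bad <- which(!(is.na(vals) | vals == 0 | vals == 1 | vals == 2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s: invalid dosage value at line %d, column %d (expected 0/1/2/NA)",
                 path, bad[1, 1] + lines_offset, bad[1, 2]), call. = FALSE)
  }
}

#' Read a PLINK .raw-style genotype table
#'
#' Whitespace-separated table with header
#' `FID IID PAT MAT SEX PHENOTYPE <snp> <snp> ...` and additive dosages
#' 0/1/2/NA. Returns a dataset fragment: the dosage matrix with missing
#' mask, sample ids (IID), and the embedded phenotype column when present
#' (all-`NA` phenotypes are treated as absent).
#'
#' @param path file path.
#' @return List with `features`, `missing_mask`, `sample_ids`, `feature_ids`,
#'   `phenotype` (or `NULL`), `sex`.
#' @export
read_plink_raw <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", "-9"))
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  .assert(identical(names(tab)[1:6], need),
          path, ": malformed header; expected columns ", paste(need, collapse = " "))
  .assert(ncol(tab) > 6, path, ": no genotype columns present")
  ids <- as.character(tab$IID)
  .assert(!anyDuplicated(ids), path, ": duplicate sample ids")
  G <- as.matrix(tab[, -(1:6), drop = FALSE])
  storage.mode(G) <- "double"
  .check_dosages(G, lines_offset = 1L, path = path)
  phen <- tab$PHENOTYPE
  if (all(is.na(phen))) phen <- NULL
  list(features = G, missing_mask = is.na(G), sample_ids = ids,
       feature_ids = colnames(G), phenotype = phen, sex = tab$SEX)
}

#' Read a delimited feature table
#'
#' Tab-separated table whose first column holds sample ids and whose
#' remaining columns are numeric features (dosages 0/1/2/NA for genotypes).
#' Comment lines starting with `#` are skipped.
#'
#' @param path file path.
#' @param dosages validate values as 0/1/2/NA genotype dosages.
#' @return List with `features`, `missing_mask`, `sample_ids`, `feature_ids`.
#' @export
read_feature_table <- function(path, dosages = TRUE) {
  .assert(file.exists(path), "file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#")
  .assert(ncol(tab) >= 2, path, ": expected an id column plus feature columns")
  ids <- as.character(tab[[1]])
  .assert(!anyDuplicated(ids), path, ": duplicate sample ids")
  G <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(G) <- "double"
  n_comments <- sum(startsWith(readLines(path, n = 200L), "#"))
  if (dosages) .check_dosages(G, lines_offset = 1L + n_comments, path = path)
  list(features = G, missing_mask = is.na(G), sample_ids = ids,
       feature_ids = colnames(G))
}

# a two-column (id, value) or (id, columns...) delimited table
.read_id_table <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#")
  .assert(ncol(tab) >= 2, path, ": expected an id column plus value column(s)")
  ids <- as.character(tab[[1]])
  .assert(!anyDuplicated(ids), path, ": duplicate sample ids")
  list(ids = ids, values = tab[, -1, drop = FALSE])
}

#' Assemble a dataset from files
#'
#' Reads genotypes (`plink_raw` or `delimited`), an optional phenotype table
#' and an optional covariate table, and aligns them by sample id. Alignment
#' is a strict id join: any id present in one file and missing in another is
#' a hard error, never a silent reorder or drop.
#'
#' @param genotypes path to the genotype file.
#' @param phenotype path to a tab-separated (id, phenotype) table; may be
#'   `NULL` for `plink_raw` input with an embedded PHENOTYPE column.
#' @param covariates path to a tab-separated (id, covariate...) table, or
#'   `NULL`.
#' @param format `"delimited"` or `"plink_raw"`.
#' @return An [dataset_bundle()].
#' @export
load_dataset <- function(genotypes, phenotype = NULL, covariates = NULL,
                         format = c("delimited", "plink_raw")) {
  format <- match.arg(format)
  frag <- if (format == "plink_raw") read_plink_raw(genotypes)
          else read_feature_table(genotypes)
  ids <- frag$sample_ids
  if (!is.null(phenotype)) {
    ph <- .read_id_table(phenotype)
    .assert(setequal(ph$ids, ids),
            "sample ids differ between genotype and phenotype files")
    y <- as.numeric(ph$values[[1]])[match(ids, ph$ids)]
  } else {
    .assert(!is.null(frag$phenotype),
            "no phenotype table given and none embedded in the genotype file")
    y <- as.numeric(frag$phenotype)
  }
  covs <- NULL
  if (!is.null(covariates)) {
    cv <- .read_id_table(covariates)
    .assert(setequal(cv$ids, ids),
            "sample ids differ between genotype and covariate files")
    covs <- as.matrix(cv$values[match(ids, cv$ids), , drop = FALSE])
    storage.mode(covs) <- "double"
  }
  dataset_bundle(frag$features, y, covariates = covs,
                 missing_mask = frag$missing_mask,
                 feature_ids = frag$feature_ids, sample_ids = ids)
}

#' Write a dataset to plain-text files
#'
#' Writes `genotypes.tsv` (sample id + one column per feature),
#' `phenotype.tsv`, `covariates.tsv` (when present) and `metadata.json`
#' (generator config, causal feature ids, MAFs, when the dataset came from
#' [generate_dataset()]) into a directory. The written files round-trip
#' through [load_dataset()] to an identical dosage matrix and mask.
#'
#' @param data an [dataset_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  .assert(inherits(data, "enpp_dataset"), "data must be a dataset_bundle()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- data.frame(sample_id = data$sample_ids,
                   data$features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(gt, file.path(dir, "genotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  ph <- data.frame(sample_id = data$sample_ids,
                   phenotype = .fmt_num(data$phenotype))
  write.table(ph, file.path(dir, "phenotype.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(data$covariates)) {
    cvm <- apply(data$covariates, 2, .fmt_num)
    cv <- data.frame(sample_id = data$sample_ids, cvm, check.names = FALSE)
    write.table(cv, file.path(dir, "covariates.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  md <- attr(data, "metadata")
  if (!is.null(md)) {
    jsonlite::write_json(md, file.path(dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Write a dataset as a PLINK .raw-style table
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE` followed by one dosage column per
#' feature (0/1/2/NA). `SEX` is taken from a covariate column named `sex`
#' (coded 1/2 as male/female from 0/1) when available, 0 otherwise.
#'
#' @param data an [dataset_bundle()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(data, path) {
  .assert(inherits(data, "enpp_dataset"), "data must be a dataset_bundle()")
  sex <- if (!is.null(data$covariates) && "sex" %in% colnames(data$covariates)) {
    as.integer(data$covariates[, "sex"]) + 1L
  } else {
    rep(0L, length(data$sample_ids))
  }
  tab <- data.frame(FID = data$sample_ids, IID = data$sample_ids,
                    PAT = 0L, MAT = 0L, SEX = sex,
                    PHENOTYPE = .fmt_num(data$phenotype),
                    data$features, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = " ", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
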