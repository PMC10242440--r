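#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

.METADATA_COLS <- c("sample_id", "dataset_id", "diet_class", "fat_pct",
                    "duration_days", "age_days", "sex", "strain", "body_site",
                    "antibiotics", "mouse_id", "timepoint")

# Clade-string helpers. Merged profiler tables encode the full taxonomy as
# "k__...|p__...|...|s__<species>|t__SGB<id>"; SGBs without a cultivated
# representative carry placeholder genus/species tokens built from GGB/SGB
# numeric identifiers rather than Linnean names.
.cladeToken <- function(clade, prefix) {
  parts <- strsplit(clade, "|", fixed = TRUE)
  vapply(parts, function(p) {
    hit <- grep(paste0("^", prefix, "__"), p, value = TRUE)
    if (length(hit)) hit[length(hit)] else ""
  }, character(1))
}

.isUnknownSGB <- function(clade) {
  sp <- sub("^s__", "", .cladeToken(clade, "s"))
  # placeholder species epithets: "GGB1234_SGB5678", bare "SGB5678", ...
  grepl("(^|_)GGB[0-9]+", sp) | grepl("(^|_)SGB[0-9]+$", sp) | !nzchar(sp)
}

.hasGenusAssigned <- function(clade) {
  g <- sub("^g__", "", .cladeToken(clade, "g"))
  nzchar(g) & !grepl("^GGB[0-9]+$", g)
}

#' Read a merged taxonomic profile table
#'
#' Parses the merged-table dialect produced by marker-based profilers: a TSV
#' whose first column \code{clade_name} holds the full taxonomy path with
#' levels separated by \code{"|"} and the terminal SGB token prefixed
#' \code{"t__"}; every remaining column is one sample of relative abundances
#' in percent. Only rows at the requested terminal level are retained, and a
#' residual \code{UNCLASSIFIED} row (if present) is dropped without
#' renormalizing, so that abundances stay comparable across samples.
#'
#' Known/unknown status (kSGB vs uSGB) is inferred from the clade naming
#' convention: features whose species epithet is a placeholder identifier
#' (\code{GGB...}/\code{SGB...}) are flagged unknown. A two-column sidecar
#' TSV (\code{feature_id}, \code{known}) can override the inference.
#'
#' @param path path to the merged profile TSV.
#' @param level taxonomic level to retain; currently only \code{"SGB"}
#'   (terminal \code{t__} rows).
#' @param metadata optional \code{data.frame} of per-sample covariates (as
#'   from \code{\link{readSampleMetadata}}) attached as \code{colData}.
#' @param sidecar optional path to a known-flag override TSV.
#' @return an \code{\link{SGBProfiles}} object.
#' @export
readMergedProfiles <- function(path, level = "SGB", metadata = NULL,
                               sidecar = NULL) {
  level <- match.arg(level)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || !(sub("^#", "", header[1]) %in% c("clade_name", "clade")))
    stop("format error: first header field must be 'clade_name'")
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("validation error: duplicate sample column(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE)
  colnames(tab)[1] <- "clade_name"
  clade <- tab$clade_name
  drop <- grepl("^UNCLASSIFIED$|^UNKNOWN$", clade, ignore.case = TRUE)
  tab <- tab[!drop, , drop = FALSE]
  clade <- clade[!drop]

  term <- vapply(strsplit(clade, "|", fixed = TRUE),
                 function(p) p[length(p)], character(1))
  keep <- grepl("^t__", term)
  tab <- tab[keep, , drop = FALSE]
  clade <- clade[keep]
  if (!nrow(tab)) stop("no terminal SGB rows found at level '", level, "'")

  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("validation error: non-numeric or missing abundance values")
  if (any(m < 0)) stop("validation error: negative abundance values")
  featureIds <- sub("^t__", "", term[keep])
  if (anyDuplicated(featureIds))
    stop("validation error: duplicate feature IDs")
  rownames(m) <- featureIds

  known <- !.isUnknownSGB(clade)
  if (!is.null(sidecar)) {
    sc <- read.delim(sidecar, stringsAsFactors = FALSE)
    stopifnot(all(c("feature_id", "known") %in% colnames(sc)))
    idx <- match(sc$feature_id, featureIds)
    known[idx[!is.na(idx)]] <- as.logical(sc$known[!is.na(idx)])
  }
  fi <- DataFrame(feature_id = featureIds,
                  clade_name = clade,
                  known = known,
                  genus_level_assigned = .hasGenusAssigned(clade),
                  row.names = featureIds)
  SGBProfiles(m, featureInfo = fi, sampleData = metadata)
}

#' Read a curated per-sample metadata table
#'
#' One row per sample; columns named exactly as the curated covariate fields
#' (\code{sample_id}, \code{dataset_id}, \code{diet_class}, \code{fat_pct},
#' \code{duration_days}, \code{age_days}, \code{sex}, \code{strain},
#' \code{body_site}, \code{antibiotics}, \code{mouse_id}, \code{timepoint});
#' missing values coded \code{NA}.
#'
#' @param path path to the metadata TSV.
#' @return a validated \code{data.frame} keyed by \code{sample_id}.
#' @export
readSampleMetadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  req <- c("sample_id", "dataset_id", "diet_class")
  if (!all(req %in% colnames(md)))
    stop("metadata must contain columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("validation error: duplicate sample_id")
  if (!all(md$diet_class %in% c("high_fat", "low_fat", NA)))
    stop("diet_class must be 'high_fat' or 'low_fat'")
  if ("fat_pct" %in% colnames(md) &&
      any(md$fat_pct < 0 | md$fat_pct > 100, na.rm = TRUE))
    stop("fat_pct must lie in [0, 100]")
  if ("antibiotics" %in% colnames(md))
    md$antibiotics <- as.logical(md$antibiotics)
  rownames(md) <- md$sample_id
  md
}

#' Write profiles / metadata in the dialects the readers accept
#'
#' @param x an \code{SGBProfiles} object.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMergedProfiles <- function(x, path) {
  out <- data.frame(clade_name = rowData(x)$clade_name,
                    abundances(x), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMergedProfiles
#' @export
writeSampleMetadata <- function(x, path) {
  md <- as.data.frame(colData(x))
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Arcsine-square-root transform of percent abundances
#'
#' Variance-stabilizing transform for compositional proportions: each percent
#' value \eqn{x} is mapped to \eqn{\arcsin\sqrt{x/100}}, giving values in
#' \eqn{[0, \pi/2]}. Shape and feature order are preserved.
#'
#' @param x numeric vector/matrix on the percent scale, or an
#'   \code{SGBProfiles} object (its \code{relabund} assay is transformed).
#' @return object of the same shape as the input abundances.
#' @export
arcsinSqrt <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- abundances(x)
  if (any(x < 0 | x > 100))
    stop("domain error: values must lie in [0, 100] percent")
  asin(sqrt(x / 100))
}

#' Per-feature prevalence across datasets
#'
#' Per-dataset prevalence is the fraction of that dataset's samples in which
#' the feature is detected (abundance strictly above \code{threshold},
#' default 0). The overall prevalence is the unweighted arithmetic mean of
#' the per-dataset values over \emph{all} analysis datasets, so a dataset in
#' which the feature is never detected contributes 0 (fixed denominator).
#'
#' @param x an \code{SGBProfiles} with \code{dataset_id} in \code{colData},
#'   or a features-x-samples matrix.
#' @param datasets dataset ID per sample (taken from \code{colData} when
#'   \code{x} is an \code{SGBProfiles}).
#' @param threshold detection threshold on the abundance scale.
#' @return a \code{DataFrame} with columns \code{feature_id}, \code{overall},
#'   \code{n_datasets_detected} and the matrix column \code{per_dataset}
#'   (features x datasets).
#' @export
computePrevalence <- function(x, datasets = NULL, threshold = 0) {
  if (is(x, "SummarizedExperiment")) {
    if (is.null(datasets)) datasets <- colData(x)$dataset_id
    x <- abundances(x)
  }
  if (is.null(datasets))
    stop("key error: dataset IDs are required (sample without metadata)")
  if (length(datasets) != ncol(x))
    stop("key error: every sample needs a dataset ID")
  datasets <- as.character(datasets)
  ds <- unique(datasets)
  det <- x > threshold
  per <- vapply(ds, function(d) rowMeans(det[, datasets == d, drop = FALSE]),
                numeric(nrow(x)))
  per <- matrix(per, nrow = nrow(x), dimnames = list(rownames(x), ds))
  DataFrame(feature_id = rownames(x),
            overall = unname(rowMeans(per)),
            n_datasets_detected = unname(rowSums(per > 0)),
            per_dataset = I(per),
            row.names = rownames(x))
}

#' Prevalence-based feature filtering
#'
#' Retains features whose overall prevalence is \emph{strictly} greater than
#' \code{minOverallPrevalence} (the ">20% prevalence" rule) and that are
#' detected in at least \code{minDatasets} datasets. Order of the input
#' table is preserved.
#'
#' @param prev a prevalence table from \code{\link{computePrevalence}}.
#' @param minOverallPrevalence fraction in [0,1]; strict lower bound.
#' @param minDatasets minimum number of datasets with detection (inclusive).
#' @return character vector of retained feature IDs (possibly empty).
#' @export
filterFeatures <- function(prev, minOverallPrevalence = 0.2, minDatasets = 5) {
  stopifnot(minOverallPrevalence >= 0, minOverallPrevalence <= 1,
            minDatasets >= 0)
  keep <- prev$overall > minOverallPrevalence &
    prev$n_datasets_detected >= minDatasets
  prev$feature_id[keep]
}

#' Per-sample kSGB/uSGB richness and abundance summaries
#'
#' @param x an \code{SGBProfiles} with \code{known} flags set.
#' @param threshold detection threshold for counting.
#' @return a \code{data.frame} with one row per sample: counts of detected
#'   kSGBs and uSGBs and their summed percent abundances.
#' @export
cohortSummaries <- function(x, threshold = 0) {
  known <- isKnown(x)
  if (anyNA(known)) stop("known flags must be set")
  a <- abundances(x)
  det <- a > threshold
  data.frame(sample_id = colnames(a),
             n_ksgb = colSums(det[known, , drop = FALSE]),
             n_usgb = colSums(det[!known, , drop = FALSE]),
             ksgb_pct = colSums(a[known, , drop = FALSE]),
             usgb_pct = colSums(a[!known, , drop = FALSE]),
             row.names = colnames(a))
}
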