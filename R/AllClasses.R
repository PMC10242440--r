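#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @import SummarizedExperiment
NULL

#' SGBProfiles: multi-cohort SGB relative-abundance container
#'
#' An S4 container for species-level genome bin (SGB) profiles across one or
#' more mouse cohorts, extending
#' \linkS4class{SummarizedExperiment}. The single assay
#' \code{"relabund"} holds relative abundances on the percent scale (each
#' column sums to at most 100; sums below 100 arise when an unclassified
#' residual fraction was dropped upstream). Feature annotation lives in
#' \code{rowData} (\code{clade_name}, \code{known}, \code{genus_level_assigned}),
#' per-sample covariates in \code{colData} (\code{dataset_id},
#' \code{diet_class}, \code{fat_pct}, \code{duration_days}, \code{age_days},
#' \code{sex}, \code{strain}, \code{body_site}, \code{antibiotics},
#' \code{mouse_id}, \code{timepoint}).
#'
#' @aliases SGBProfiles-class
#' @exportClass SGBProfiles
setClass("SGBProfiles", contains = "SummarizedExperiment")

.validSGBProfiles <- function(object) {
  msg <- NULL
  if (!("relabund" %in% assayNames(object)))
    msg <- c(msg, "assay 'relabund' is required")
  else {
    a <- assay(object, "relabund")
    if (anyNA(a))
      msg <- c(msg, "abundances must not contain NA")
    else {
      if (any(a < 0))
        msg <- c(msg, "abundances must be non-negative")
      cs <- colSums(a)
      if (any(cs > 100 + 1e-6))
        msg <- c(msg, "per-sample abundance sums must not exceed 100 (percent scale)")
    }
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample IDs must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature IDs must be unique")
  rd <- rowData(object)
  if ("clade_name" %in% colnames(rd) && any(!nzchar(rd$clade_name)))
    msg <- c(msg, "clade_name must be non-empty")
  if (is.null(msg)) TRUE else msg
}

setValidity("SGBProfiles", .validSGBProfiles)

#' Construct an SGBProfiles object
#'
#' @param abundances numeric matrix, features x samples, percent scale
#'   (per-sample column sums at most 100). Row names are SGB feature IDs,
#'   column names sample IDs.
#' @param featureInfo a \code{data.frame}/\code{DataFrame} of per-feature
#'   annotation with at least \code{clade_name} (full taxonomy string),
#'   \code{known} (logical, kSGB vs uSGB) and optionally
#'   \code{genus_level_assigned}. Defaults to minimal annotation.
#' @param sampleData a \code{data.frame}/\code{DataFrame} of per-sample
#'   covariates (see class description), one row per sample of
#'   \code{abundances}, keyed by \code{sample_id} or row names.
#'
#' @return an \code{SGBProfiles} object.
#' @export
SGBProfiles <- function(abundances, featureInfo = NULL, sampleData = NULL) {
  abundances <- as.matrix(abundances)
  if (is.null(rownames(abundances)))
    stop("abundances must have feature IDs as row names")
  if (is.null(colnames(abundances)))
    stop("abundances must have sample IDs as column names")
  if (is.null(featureInfo)) {
    featureInfo <- DataFrame(clade_name = rownames(abundances),
                             known = NA,
                             genus_level_assigned = NA,
                             row.names = rownames(abundances))
  } else {
    featureInfo <- DataFrame(featureInfo)
    if (is.null(rownames(featureInfo)) || all(rownames(featureInfo) == as.character(seq_len(nrow(featureInfo))))) {
      if ("feature_id" %in% colnames(featureInfo))
        rownames(featureInfo) <- featureInfo$feature_id
      else rownames(featureInfo) <- rownames(abundances)
    }
    featureInfo <- featureInfo[rownames(abundances), , drop = FALSE]
  }
  if (is.null(sampleData)) {
    sampleData <- DataFrame(row.names = colnames(abundances))
  } else {
    sampleData <- DataFrame(sampleData)
    if ("sample_id" %in% colnames(sampleData))
      rownames(sampleData) <- sampleData$sample_id
    missing <- setdiff(colnames(abundances), rownames(sampleData))
    if (length(missing))
      stop("samples without metadata: ", paste(head(missing, 5), collapse = ", "))
    sampleData <- sampleData[colnames(abundances), , drop = FALSE]
  }
  se <- SummarizedExperiment(assays = SimpleList(relabund = abundances),
                             rowData = featureInfo, colData = sampleData)
  new("SGBProfiles", se)
}

#' @describeIn SGBProfiles the relative-abundance matrix (percent scale).
#' @param x an \code{SGBProfiles} object.
#' @export
abundances <- function(x) {
  stopifnot(is(x, "SummarizedExperiment"))
  assay(x, "relabund")
}

#' @describeIn SGBProfiles per-feature annotation as a \code{DataFrame}.
#' @export
featureInfo <- function(x) rowData(x)

#' @describeIn SGBProfiles logical vector flagging known SGBs (kSGBs).
#' @export
isKnown <- function(x) {
  k <- rowData(x)$known
  if (is.null(k)) stop("known/unknown flags are not set on this object")
  as.logical(k)
}

setMethod("show", "SGBProfiles", function(object) {
  cat("SGBProfiles:", nrow(object), "SGBs x", ncol(object), "samples\n")
  k <- rowData(object)$known
  if (!is.null(k) && !all(is.na(k)))
    cat("  kSGBs:", sum(k, na.rm = TRUE), " uSGBs:", sum(!k, na.rm = TRUE), "\n")
  ds <- colData(object)$dataset_id
  if (!is.null(ds))
    cat("  datasets:", length(unique(ds)), paste0("(", paste(head(unique(ds), 6), collapse = ", "),
        if (length(unique(ds)) > 6) ", ..." else "", ")"), "\n")
  invisible(NULL)
})
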