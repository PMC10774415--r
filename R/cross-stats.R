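## Statistics over cross-progeny count tables: super-Mendelian transmission
## rates with score intervals, chi-square goodness of fit against a binary
## Mendelian expectation, inversion of the hemizygote transmission model to
## recover cleavage and HDR rates, and composition of conditional phenotype
## fractions.

#' Cross-progeny count tables
#'
#' A `CrossCounts` holds progeny counts of one cross experiment, classified
#' by fluorescent-marker status (`POSITIVE`/`NEGATIVE` for carrying the
#' construct), phenotypic sex (`MALE`/`FEMALE`/`INTERSEX`, or `NA` when not
#' scored) and eye-colour phenotype (`RED`/`MOSAIC`/`WHITE`, or `NA`), per
#' replicate, together with the cross metadata (which parent was transgenic
#' and whether the mate was wild type or an eye-colour mutant).
#'
#' @param counts Data.frame with columns `replicate`, `marker`,
#'   `sex_phenotype`, `eye_phenotype`, `count`.
#' @param parentSex `"female"` or `"male"`: the transgenic parent.
#' @param mateType `"WILD_TYPE"` or `"EYE_MUTANT"`.
#' @param trueParams Optional [driveParams()] that generated the table
#'   (synthetic data), for parameter-recovery tests.
#' @param design Optional [driveDesign()].
#' @param x A `CrossCounts`.
#' @return `crossCounts()` returns a `CrossCounts` object.
#' @export
crossCounts <- function(counts, parentSex, mateType, trueParams = NULL,
                        design = NULL) {
  counts$replicate <- as.integer(counts$replicate)
  counts$count <- as.integer(counts$count)
  obj <- new("CrossCounts", counts = counts, parentSex = parentSex,
             mateType = mateType, trueParams = trueParams, design = design)
  validObject(obj)
  obj
}

#' @rdname crossCounts
#' @export
setMethod("countsTable", "CrossCounts", function(x) x@counts)
#' @rdname crossCounts
#' @export
setMethod("totalProgeny", "CrossCounts", function(x) sum(x@counts$count))
#' @rdname crossCounts
#' @export
setMethod("markerPositive", "CrossCounts",
          function(x) sum(x@counts$count[x@counts$marker == "POSITIVE"]))
#' @rdname crossCounts
#' @export
setMethod("parentSex", "CrossCounts", function(x) x@parentSex)
#' @rdname crossCounts
#' @export
setMethod("mateType", "CrossCounts", function(x) x@mateType)
#' @rdname crossCounts
#' @export
setMethod("trueParams", "CrossCounts", function(x) x@trueParams)

setMethod("show", "CrossCounts", function(object) {
  cat(sprintf("CrossCounts: transgenic %s x %s mate, %d progeny, %d replicates\n",
              object@parentSex, tolower(object@mateType),
              totalProgeny(object), length(unique(object@counts$replicate))))
  pos <- markerPositive(object)
  cat(sprintf("  marker-positive: %d (%.1f%%)\n", pos,
              100 * pos / max(1, totalProgeny(object))))
})

#' Drive transmission rate with score interval
#'
#' The fraction of progeny carrying the drive marker, with a 95% Wilson
#' score confidence interval. 50% is the Mendelian expectation from a
#' hemizygous parent; values above are super-Mendelian.
#'
#' @param positive Number of marker-positive progeny.
#' @param total Total progeny scored; must be positive.
#' @param conf Confidence level (default 0.95).
#' @return List with `proportion`, `conf_int` (length-2 vector), `positive`,
#'   `total`.
#' @export
#' @examples
#' transmissionRate(856, 1000)$proportion  # 0.856
transmissionRate <- function(positive, total, conf = 0.95) {
  if (length(total) != 1 || total <= 0)
    stop("'total' must be a single positive count")
  if (positive < 0 || positive > total)
    stop("'positive' must lie in [0, total]")
  ci <- prop.test(positive, total, correct = FALSE,
                  conf.level = conf)$conf.int
  list(proportion = positive / total, conf_int = as.numeric(ci),
       positive = positive, total = total)
}

#' Chi-square goodness of fit against a binary expectation
#'
#' One-degree-of-freedom chi-square test of an observed binary split against
#' an expected proportion (e.g. observed transmission against the Mendelian
#' 0.5), without continuity correction.
#'
#' @param observed Observed count in the focal category.
#' @param total Total count.
#' @param expectedProportion Expected proportion of the focal category.
#' @return List with `statistic`, `p_value`, `df` (always 1).
#' @export
#' @examples
#' chisqGof(600, 1000, 0.5)$statistic  # 40
chisqGof <- function(observed, total, expectedProportion) {
  if (length(total) != 1 || total <= 0) stop("'total' must be positive")
  if (observed < 0 || observed > total)
    stop("'observed' must lie in [0, total]")
  if (expectedProportion < 0 || expectedProportion > 1)
    stop("'expectedProportion' must be a probability")
  expected <- total * c(expectedProportion, 1 - expectedProportion)
  if (min(expected) < 1)
    stop("expected count below 1; the chi-square approximation is invalid")
  ht <- suppressWarnings(chisq.test(c(observed, total - observed),
                                    p = c(expectedProportion,
                                          1 - expectedProportion),
                                    correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value), df = 1L)
}

#' Infer cleavage and HDR rates from cross fractions
#'
#' Inverts the hemizygous-parent germline model. With cleavage rate c and
#' HDR rate h, the marker transmission rate is `T = (1 + c h) / 2` and —
#' assuming every NHEJ repair disrupts the scored phenotype gene (r2 = 1) —
#' the mutant fraction among marker-negative progeny is
#' `m = c (1 - h) / (1 - c h)`. Solving gives
#' `c = (2T - 1) + m (2 - 2T)` and `h = (2T - 1) / c`, with h indeterminate
#' (`NA`) when c = 0.
#'
#' @param transmission Observed marker-positive proportion, in `[0.5, 1]`
#'   (the model cannot produce sub-Mendelian transmission).
#' @param mutantFraction Mutant (phenotype-disrupted) fraction among
#'   marker-negative progeny, in `[0, 1]`.
#' @return List with `cleavage` and `hdr`.
#' @export
#' @examples
#' infer <- inferCleavageHdr(0.856, 0.747)
#' round(c(infer$cleavage, infer$hdr), 3)  # 0.927 0.768
inferCleavageHdr <- function(transmission, mutantFraction) {
  if (transmission < 0.5 || transmission > 1)
    stop("'transmission' must lie in [0.5, 1]")
  if (mutantFraction < 0 || mutantFraction > 1)
    stop("'mutantFraction' must lie in [0, 1]")
  c_ <- (2 * transmission - 1) + mutantFraction * (2 - 2 * transmission)
  h <- if (c_ == 0) NA_real_ else (2 * transmission - 1) / c_
  list(cleavage = c_, hdr = h)
}

#' Compose an overall fraction from conditional fractions
#'
#' Law of total probability over the binary marker split: the overall
#' fraction of a phenotype equals
#' `pPositive * fPositive + (1 - pPositive) * fNegative`.
#'
#' @param pPositive Marker-positive proportion of the progeny.
#' @param fPositive Phenotype fraction among marker-positive progeny.
#' @param fNegative Phenotype fraction among marker-negative progeny.
#' @return The overall phenotype fraction.
#' @export
#' @examples
#' overallFraction(0.831, 0.646, 0.447)  # about 0.612
overallFraction <- function(pPositive, fPositive, fNegative) {
  for (v in c(pPositive, fPositive, fNegative))
    if (v < 0 || v > 1) stop("all inputs must be proportions in [0, 1]")
  pPositive * fPositive + (1 - pPositive) * fNegative
}

#' Per-replicate and pooled cross statistics
#'
#' Computes the transmission rate and — when eye phenotypes were scored —
#' the mutant (non-red) fraction among marker-negative progeny, both per
#' replicate and on the pooled counts. Published cross tables mix means of
#' replicate rates with pooled tests, so both are reported, labelled.
#'
#' @param x A [crossCounts()] object.
#' @return List with `pooled` (list: `transmission`, `mutant_fraction_neg`,
#'   `total`) and `per_replicate` (data.frame), plus
#'   `mean_of_replicates` (transmission).
#' @export
crossSummary <- function(x) {
  stopifnot(is(x, "CrossCounts"))
  tab <- x@counts
  one <- function(d) {
    total <- sum(d$count)
    pos <- sum(d$count[d$marker == "POSITIVE"])
    neg <- d[d$marker == "NEGATIVE", ]
    negTotal <- sum(neg$count)
    scored <- !all(is.na(neg$eye_phenotype))
    mut <- if (scored && negTotal > 0)
      sum(neg$count[!is.na(neg$eye_phenotype) & neg$eye_phenotype != "RED"]) /
        negTotal
    else NA_real_
    c(total = total, positive = pos,
      transmission = if (total > 0) pos / total else NA_real_,
      mutant_fraction_neg = mut)
  }
  pooled <- one(tab)
  reps <- sort(unique(tab$replicate))
  per <- do.call(rbind, lapply(reps, function(r) one(tab[tab$replicate == r, ])))
  per <- data.frame(replicate = reps, per)
  list(pooled = as.list(pooled),
       per_replicate = per,
       mean_of_replicates = mean(per$transmission, na.rm = TRUE))
}

#' Read / write cross count tables
#'
#' Tidy TSV dialect: one row per replicate x category with columns
#' `replicate`, `marker`, `sex_phenotype`, `eye_phenotype`, `count`
#' (`NA` for unscored phenotype axes), preceded by `#` header comments
#' recording the cross metadata. The reader validates categories and
#' nonnegative integer counts.
#'
#' @param x A `CrossCounts`.
#' @param path File path.
#' @return `readCrossCounts()` returns a `CrossCounts`;
#'   `writeCrossCounts()` returns `path` invisibly.
#' @export
writeCrossCounts <- function(x, path) {
  stopifnot(is(x, "CrossCounts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# parent_sex: ", x@parentSex),
               paste0("# mate_type: ", x@mateType)), con)
  if (!is.null(x@trueParams))
    writeLines(sprintf("# true_params: cleavage=%.17g hdr=%.17g r2=%.17g k=%.17g",
                       x@trueParams@cleavage, x@trueParams@hdr,
                       x@trueParams@r2, x@trueParams@maternalFactor), con)
  if (!is.null(x@design))
    writeLines(paste0("# design: ", designName(x@design)), con)
  write.table(x@counts, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCrossCounts
#' @export
readCrossCounts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  header <- grep("^#", readLines(path, n = 10), value = TRUE)
  meta <- function(key, default = NA_character_) {
    hit <- grep(paste0("^# ", key, ": "), header, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1]) else default
  }
  counts <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                       na.strings = "NA")
  needed <- c("replicate", "marker", "sex_phenotype", "eye_phenotype", "count")
  missing <- setdiff(needed, names(counts))
  if (length(missing))
    stop("counts table is missing columns: ", paste(missing, collapse = ", "))
  if (any(counts$count != floor(counts$count)) || any(counts$count < 0))
    stop("counts must be nonnegative integers")
  tp <- meta("true_params")
  trueParams <- if (!is.na(tp)) {
    vals <- as.numeric(sub(".*=", "",
                           strsplit(tp, " ", fixed = TRUE)[[1]]))
    driveParams(vals[1], vals[2], vals[3], vals[4])
  } else NULL
  dn <- meta("design")
  crossCounts(counts,
              parentSex = meta("parent_sex", "female"),
              mateType = meta("mate_type", "WILD_TYPE"),
              trueParams = trueParams,
              design = if (!is.na(dn)) driveDesign(dn) else NULL)
}
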