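#' @rdname driveParams
#' @export
setGeneric("cleavageRate", function(x) standardGeneric("cleavageRate"))
#' @rdname driveParams
#' @export
setGeneric("hdrRate", function(x) standardGeneric("hdrRate"))
#' @rdname driveParams
#' @export
setGeneric("r2Fraction", function(x) standardGeneric("r2Fraction"))
#' @rdname driveParams
#' @export
setGeneric("maternalFactor", function(x) standardGeneric("maternalFactor"))

#' @rdname driveDesign
#' @export
setGeneric("designName", function(x) standardGeneric("designName"))
#' @rdname driveDesign
#' @export
setGeneric("homeLocus", function(x) standardGeneric("homeLocus"))
#' @rdname driveDesign
#' @export
setGeneric("transTarget", function(x) standardGeneric("transTarget"))
#' @rdname driveDesign
#' @export
setGeneric("targetedLoci", function(x) standardGeneric("targetedLoci"))
#' @rdname driveDesign
#' @export
setGeneric("fertilityLoci", function(x) standardGeneric("fertilityLoci"))
#' @rdname driveDesign
#' @export
setGeneric("targetsTra", function(x) standardGeneric("targetsTra"))

#' @rdname simResult
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))
#' @rdname simResult
#' @export
setGeneric("isExtinct", function(x) standardGeneric("isExtinct"))
#' @rdname simResult
#' @export
setGeneric("extinctionGeneration", function(x) standardGeneric("extinctionGeneration"))

#' @rdname crossCounts
#' @export
setGeneric("countsTable", function(x) standardGeneric("countsTable"))
#' @rdname crossCounts
#' @export
setGeneric("totalProgeny", function(x) standardGeneric("totalProgeny"))
#' @rdname crossCounts
#' @export
setGeneric("markerPositive", function(x) standardGeneric("markerPositive"))
#' @rdname crossCounts
#' @export
setGeneric("parentSex", function(x) standardGeneric("parentSex"))
#' @rdname crossCounts
#' @export
setGeneric("mateType", function(x) standardGeneric("mateType"))
#' @rdname crossCounts
#' @export
setGeneric("trueParams", function(x) standardGeneric("trueParams"))
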