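#' @rdname GenotypeMatrix-class
#' @param x a `GenotypeMatrix`
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))

#' @rdname GenotypeMatrix-class
#' @param value replacement roles (named character, or unnamed in sample
#'   order)
#' @export
setGeneric("sampleRoles<-",
           function(x, value) standardGeneric("sampleRoles<-"))

#' @rdname MixtureFit-class
#' @param object a `MixtureFit`
#' @export
setGeneric("tauG", function(object) standardGeneric("tauG"))

#' @rdname MixtureFit-class
#' @export
setGeneric("tauR", function(object) standardGeneric("tauR"))

#' @rdname MixtureFit-class
#' @export
setGeneric("mixingProportion",
           function(object) standardGeneric("mixingProportion"))

#' @rdname MixtureFit-class
#' @export
setGeneric("responsibilities",
           function(object) standardGeneric("responsibilities"))

#' @rdname MixtureFit-class
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))
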