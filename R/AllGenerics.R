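#' @import methods
#' @importFrom BiocGenerics counts
#' @importFrom stats p.adjust pbinom rnorm runif t.test var setNames
#' @importFrom utils head read.delim write.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib grnDoE, .registration = TRUE
NULL

#' @rdname grn-accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname grn-accessors
#' @export
setGeneric("stimulusNames", function(x) standardGeneric("stimulusNames"))

#' @rdname grn-accessors
#' @export
setGeneric("geneInteractions", function(x) standardGeneric("geneInteractions"))

#' @rdname grn-accessors
#' @export
setGeneric("geneInteractions<-",
           function(x, value) standardGeneric("geneInteractions<-"))

#' @rdname grn-accessors
#' @export
setGeneric("stimulusInteractions",
           function(x) standardGeneric("stimulusInteractions"))

#' @rdname grn-accessors
#' @export
setGeneric("stimulusInteractions<-",
           function(x, value) standardGeneric("stimulusInteractions<-"))

#' @rdname grn-accessors
#' @export
setGeneric("kinetics", function(x) standardGeneric("kinetics"))

#' @rdname grn-accessors
#' @export
setGeneric("kinetics<-", function(x, value) standardGeneric("kinetics<-"))

#' @rdname grn-accessors
#' @export
setGeneric("proteinThresholds", function(x) standardGeneric("proteinThresholds"))

#' @rdname grn-accessors
#' @export
setGeneric("stimulusThresholds",
           function(x) standardGeneric("stimulusThresholds"))

#' @rdname grn-accessors
#' @export
setGeneric("hillExponent", function(x) standardGeneric("hillExponent"))

#' @rdname grn-accessors
#' @export
setGeneric("knockedOut", function(x) standardGeneric("knockedOut"))

#' @rdname grn-accessors
#' @export
setGeneric("stimulusProfiles", function(x) standardGeneric("stimulusProfiles"))

#' @rdname grn-accessors
#' @export
setGeneric("stimulusProfiles<-",
           function(x, value) standardGeneric("stimulusProfiles<-"))

#' @rdname CountMatrix
#' @export
setGeneric("timeStamp", function(x) standardGeneric("timeStamp"))

#' @rdname CountMatrix
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname pooledPrediction
#' @export
setGeneric("pooledPrediction",
           function(x, ...) standardGeneric("pooledPrediction"))

#' @rdname perturbationEntropy
#' @export
setGeneric("perturbationEntropy",
           function(x, ...) standardGeneric("perturbationEntropy"))
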