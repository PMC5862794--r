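#' @import methods
#' @importFrom stats rbinom runif rbeta setNames quantile
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' @export
setGeneric("calls", function(x, ...) standardGeneric("calls"))

#' @export
setGeneric("snpMap", function(x, ...) standardGeneric("snpMap"))

#' @export
setGeneric("sampleInfo", function(x, ...) standardGeneric("sampleInfo"))

#' @export
setGeneric("panelIndex", function(x, panel = "icbf800", ...)
  standardGeneric("panelIndex"))
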