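## Re-exported generics so downstream code can use the container without
## attaching SummarizedExperiment explicitly.

#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @importFrom SummarizedExperiment colData<-
#' @export
SummarizedExperiment::`colData<-`

#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay

#' @importFrom SummarizedExperiment assayNames
#' @export
SummarizedExperiment::assayNames

#' @importFrom S4Vectors mcols
#' @export
S4Vectors::mcols

#' @importFrom S4Vectors mcols<-
#' @export
S4Vectors::`mcols<-`

#' @importFrom GenomicRanges GRanges
#' @export
GenomicRanges::GRanges
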