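#' Re-exports
#'
#' Accessors re-exported so SpectrumSet metadata can be reached without
#' attaching SummarizedExperiment.
#' @name reexports
#' @keywords internal
NULL

#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @importFrom S4Vectors metadata
#' @export
S4Vectors::metadata
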