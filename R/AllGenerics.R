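#' @import methods
NULL

#' Patient identifier of a feature container
#'
#' @param object a [PatchFeatureSet-class] or [DEFeatureSet-class].
#' @return A single character scalar.
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))

#' Numeric feature matrix of a container
#'
#' @param object a [PatchFeatureSet-class] or [DEFeatureSet-class].
#' @return A numeric matrix, one row per patch.
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' Identifier of the backbone that produced a feature set
#'
#' @param object a [PatchFeatureSet-class].
#' @return A character scalar naming the feature source.
#' @export
setGeneric("backboneId", function(object) standardGeneric("backboneId"))

#' Indices selected by stability selection
#'
#' @param object a [SelectionResult-class] or [RiskModel-class].
#' @return Integer vector of 1-based feature indices.
#' @export
setGeneric("selectedIdx", function(object) standardGeneric("selectedIdx"))

#' Per-feature selection frequencies
#'
#' @param object a [SelectionResult-class].
#' @return Integer vector: for each feature, the number of subsample
#'   repeats in which its elasticnet-Cox coefficient was nonzero.
#' @export
setGeneric("selectionFrequency",
           function(object) standardGeneric("selectionFrequency"))
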