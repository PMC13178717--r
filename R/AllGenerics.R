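# Generics. Accessor generics are defined here; methods live beside the class
# constructors in the module files.

#' @export
setGeneric("nyquistCpi", function(x) standardGeneric("nyquistCpi"))

#' @export
setGeneric("radialFreq", function(x) standardGeneric("radialFreq"))

#' @export
setGeneric("maskWeights", function(x) standardGeneric("maskWeights"))

#' @export
setGeneric("maskCondition", function(x) standardGeneric("maskCondition"))

#' @export
setGeneric("invertMask", function(mask) standardGeneric("invertMask"))

#' @export
setGeneric("bandEdges", function(x) standardGeneric("bandEdges"))

#' @export
setGeneric("bandLabels", function(x) standardGeneric("bandLabels"))

#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @export
setGeneric("profileProportions", function(x) standardGeneric("profileProportions"))

#' @export
setGeneric("deltaAUC", function(x) standardGeneric("deltaAUC"))

#' @export
setGeneric("epsilons", function(x) standardGeneric("epsilons"))

#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))

#' @export
setGeneric("cleanAccuracy", function(x) standardGeneric("cleanAccuracy"))

#' @export
setGeneric("robustAUC", function(curve) standardGeneric("robustAUC"))

#' @export
setGeneric("dissimilarities", function(x) standardGeneric("dissimilarities"))

#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' @export
setGeneric("responseValues", function(x) standardGeneric("responseValues"))

#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' @export
setGeneric("templates", function(x) standardGeneric("templates"))

#' Model interface: logits, class predictions, features, input gradients
#'
#' Every classifier usable with the attack and RSA stages implements these
#' four generics. `X` may be a single H x W x 3 image array or a matrix with
#' one flattened image per row (column-major flattening of the array).
#'
#' @param model a classifier ([MLPClassifier-class] or
#'   [LinearClassifier-class])
#' @param X image(s): H x W x 3 array or n x D matrix of flattened pixels
#' @param y integer class labels (for [inputGradient()])
#' @return `predictLogits`: n x K logit matrix. `predictClasses`: integer
#'   vector of top-1 class indices. `penultimateFeatures`: n x H matrix of
#'   features feeding the final linear layer. `inputGradient`: n x D matrix of
#'   gradients of the cross-entropy loss with respect to the input pixels.
#' @name model-interface
NULL

#' @rdname model-interface
#' @export
setGeneric("predictLogits", function(model, X) standardGeneric("predictLogits"))

#' @rdname model-interface
#' @export
setGeneric("predictClasses", function(model, X)
  standardGeneric("predictClasses"))

#' @rdname model-interface
#' @export
setGeneric("penultimateFeatures", function(model, X)
  standardGeneric("penultimateFeatures"))

#' @rdname model-interface
#' @export
setGeneric("inputGradient", function(model, X, y)
  standardGeneric("inputGradient"))
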