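#' @rdname Interactome-class
#' @param x An object.
#' @export
setGeneric("interactomeGenes", function(x) standardGeneric("interactomeGenes"))

#' @rdname Interactome-class
#' @export
setGeneric("interactomeEdges", function(x) standardGeneric("interactomeEdges"))

#' @rdname GeneNetwork-class
#' @param x An object.
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("nodeRoles", function(x) standardGeneric("nodeRoles"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("isolatedSeeds", function(x) standardGeneric("isolatedSeeds"))

#' @rdname AnnotationCollection-class
#' @param x An object.
#' @export
setGeneric("annotationCategory", function(x) standardGeneric("annotationCategory"))

#' @rdname AnnotationCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname DrugEffectTable-class
#' @param x An object.
#' @export
setGeneric("drugEffects", function(x) standardGeneric("drugEffects"))

#' @rdname ScoreBreakdown-class
#' @param x An object.
#' @export
setGeneric("scoreTotal", function(x) standardGeneric("scoreTotal"))

#' @rdname ScoreBreakdown-class
#' @export
setGeneric("scoreApplied", function(x) standardGeneric("scoreApplied"))

#' @rdname ModuleAssignment-class
#' @param x An object.
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))
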