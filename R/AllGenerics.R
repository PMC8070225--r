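#' Accessors for ClusterRegion objects
#'
#' Read access to the slots of a [ClusterRegion-class] and replacement
#' methods for the annotations filled in along the pipeline.
#'
#' @param x a \code{ClusterRegion}
#' @param value replacement value
#' @return the slot value, or the modified object for replacement forms
#' @name ClusterRegion-accessors
#' @aliases clusterId assemblyId regionGenes assignedType assignedType<-
#'   hybridTypes hybridTypes<- coreFamilies coreFamilies<-
NULL

#' @rdname ClusterRegion-accessors
#' @export
setGeneric("clusterId", function(x) standardGeneric("clusterId"))
#' @rdname ClusterRegion-accessors
#' @export
setGeneric("assemblyId", function(x) standardGeneric("assemblyId"))
#' @rdname ClusterRegion-accessors
#' @export
setGeneric("regionGenes", function(x) standardGeneric("regionGenes"))
#' @rdname ClusterRegion-accessors
#' @export
setGeneric("assignedType", function(x) standardGeneric("assignedType"))
#' @rdname ClusterRegion-accessors
#' @export
setGeneric("assignedType<-", function(x, value)
  standardGeneric("assignedType<-"))
#' @rdname ClusterRegion-accessors
#' @export
setGeneric("hybridTypes", function(x) standardGeneric("hybridTypes"))
#' @rdname ClusterRegion-accessors
#' @export
setGeneric("hybridTypes<-", function(x, value)
  standardGeneric("hybridTypes<-"))
#' @rdname ClusterRegion-accessors
#' @export
setGeneric("coreFamilies", function(x) standardGeneric("coreFamilies"))
#' @rdname ClusterRegion-accessors
#' @export
setGeneric("coreFamilies<-", function(x, value)
  standardGeneric("coreFamilies<-"))

setMethod("clusterId", "ClusterRegion", function(x) x@cluster_id)
setMethod("assemblyId", "ClusterRegion", function(x) x@assembly_id)
setMethod("regionGenes", "ClusterRegion", function(x) x@genes)
setMethod("assignedType", "ClusterRegion", function(x) x@assigned_type)
setMethod("assignedType<-", "ClusterRegion", function(x, value) {
  x@assigned_type <- value
  methods::validObject(x)
  x
})
setMethod("hybridTypes", "ClusterRegion", function(x) x@hybrid_types)
setMethod("hybridTypes<-", "ClusterRegion", function(x, value) {
  x@hybrid_types <- value
  x
})
setMethod("coreFamilies", "ClusterRegion", function(x) x@core_families)
setMethod("coreFamilies<-", "ClusterRegion", function(x, value) {
  x@core_families <- value
  x
})
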