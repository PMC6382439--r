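#' Accessors for latent embeddings
#'
#' @param object a [LatentEmbedding-class].
#' @return `latentCoords`: cells x dimensions matrix. `relevance`: per-
#'   dimension ARD weight vector. `partitionRelevance`: partitions x
#'   dimensions weight matrix (partitioned fits only). `adaptationLV`: the
#'   oriented 1-D adaptation coordinate.
#' @name LatentEmbedding-accessors
NULL

#' @rdname LatentEmbedding-accessors
#' @export
setGeneric("latentCoords", function(object) standardGeneric("latentCoords"))

#' @rdname LatentEmbedding-accessors
#' @export
setGeneric("relevance", function(object) standardGeneric("relevance"))

#' @rdname LatentEmbedding-accessors
#' @export
setGeneric("partitionRelevance",
           function(object) standardGeneric("partitionRelevance"))

#' @rdname LatentEmbedding-accessors
#' @export
setGeneric("adaptationLV", function(object) standardGeneric("adaptationLV"))

#' @rdname LatentEmbedding-accessors
#' @export
setMethod("latentCoords", "LatentEmbedding", function(object) object@X)

#' @rdname LatentEmbedding-accessors
#' @export
setMethod("relevance", "LatentEmbedding", function(object) object@relevance)

#' @rdname LatentEmbedding-accessors
#' @export
setMethod("partitionRelevance", "LatentEmbedding",
          function(object) object@partitionRelevance)

#' @rdname LatentEmbedding-accessors
#' @export
setMethod("adaptationLV", "LatentEmbedding", function(object) {
    if (is.na(object@adaptationDim)) {
        stop("no adaptation dimension selected; run selectAdaptationLV()")
    }
    lv <- object@X[, object@adaptationDim] * object@orientation
    names(lv) <- rownames(object@X)
    lv
})
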