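#' Accessors for tiger objects
#'
#' \code{tfNames} / \code{targetNames} return the TF and target-gene
#' identifiers; \code{edgeCount} the number of nonzero prior edges;
#' \code{priorSigns} the signed sparse adjacency; \code{networkWeights} the
#' posterior mean regulatory network W; \code{activities} the posterior mean
#' TF activities Z; \code{elboTrace} the recorded ELBO trace;
#' \code{noiseVariance} the posterior mean of the noise variance;
#' \code{familyCounts} the number of edges per constraint family.
#'
#' @param x a \linkS4class{PriorNetwork}, \linkS4class{ConstraintTable} or
#'   \linkS4class{TigerFit}.
#' @return see the individual accessor descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tfNames", function(x) standardGeneric("tfNames"))
#' @rdname accessors
#' @export
setGeneric("targetNames", function(x) standardGeneric("targetNames"))
#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname accessors
#' @export
setGeneric("priorSigns", function(x) standardGeneric("priorSigns"))
#' @rdname accessors
#' @export
setGeneric("networkWeights", function(x) standardGeneric("networkWeights"))
#' @rdname accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))
#' @rdname accessors
#' @export
setGeneric("elboTrace", function(x) standardGeneric("elboTrace"))
#' @rdname accessors
#' @export
setGeneric("noiseVariance", function(x) standardGeneric("noiseVariance"))
#' @rdname accessors
#' @export
setGeneric("familyCounts", function(x) standardGeneric("familyCounts"))
#' @rdname accessors
#' @export
setGeneric("constraintFamilies", function(x) standardGeneric("constraintFamilies"))

#' @rdname accessors
#' @export
setMethod("tfNames", "PriorNetwork", function(x) colnames(x@signs))
#' @rdname accessors
#' @export
setMethod("targetNames", "PriorNetwork", function(x) rownames(x@signs))
#' @rdname accessors
#' @export
setMethod("edgeCount", "PriorNetwork", function(x) length(x@signs@x))
#' @rdname accessors
#' @export
setMethod("priorSigns", "PriorNetwork", function(x) x@signs)

#' @rdname accessors
#' @export
setMethod("tfNames", "ConstraintTable", function(x) colnames(x@family))
#' @rdname accessors
#' @export
setMethod("targetNames", "ConstraintTable", function(x) rownames(x@family))
#' @rdname accessors
#' @export
setMethod("priorSigns", "ConstraintTable", function(x) x@priorSigns)
#' @rdname accessors
#' @export
setMethod("constraintFamilies", "ConstraintTable", function(x) {
  f <- matrix(.FAMILY_LEVELS[x@family + 1L], nrow(x@family),
              dimnames = dimnames(x@family))
  f
})
#' @rdname accessors
#' @export
setMethod("familyCounts", "ConstraintTable", function(x) {
  cnt <- tabulate(x@family + 1L, nbins = 4L)
  names(cnt) <- .FAMILY_LEVELS
  cnt
})

#' @rdname accessors
#' @export
setMethod("networkWeights", "TigerFit", function(x) x@W_mean)
#' @rdname accessors
#' @export
setMethod("activities", "TigerFit", function(x) x@Z_mean)
#' @rdname accessors
#' @export
setMethod("elboTrace", "TigerFit", function(x) x@elbo_trace)
#' @rdname accessors
#' @export
setMethod("noiseVariance", "TigerFit", function(x) x@sigma_eps2_mean)
#' @rdname accessors
#' @export
setMethod("familyCounts", "TigerFit", function(x) x@constraint_counts)

setMethod("show", "PriorNetwork", function(object) {
  s <- object@signs
  cat(sprintf("PriorNetwork: %d genes x %d TFs, %d signed edges (%d+, %d-)\n",
              nrow(s), ncol(s), length(s@x), sum(s@x > 0), sum(s@x < 0)))
})

setMethod("show", "ConstraintTable", function(object) {
  cnt <- familyCounts(object)
  cat(sprintf("ConstraintTable: %d genes x %d TFs (|pcor| threshold %g)\n",
              nrow(object@family), ncol(object@family), object@threshold))
  cat(sprintf("  POS_HALF_NORMAL %d | NEG_HALF_NORMAL %d | FREE_NORMAL %d | ZERO %d\n",
              cnt["POS_HALF_NORMAL"], cnt["NEG_HALF_NORMAL"],
              cnt["FREE_NORMAL"], cnt["ZERO"]))
})

setMethod("show", "TigerFit", function(object) {
  cat(sprintf("TigerFit (%s): %d genes x %d TFs x %d samples\n",
              object@method, nrow(object@W_mean), ncol(object@W_mean),
              ncol(object@Z_mean)))
  cat(sprintf("  %d free parameters over %d edges; sigma_eps2 = %.4g\n",
              2L * length(object@alpha_mean) + length(object@Z_mean) + 1L,
              length(object@alpha_mean), object@sigma_eps2_mean))
  if (length(object@elbo_trace))
    cat(sprintf("  ELBO %.2f after %d iterations (converged: %s)\n",
                utils::tail(object@elbo_trace, 1), object@iterations,
                object@converged))
})

setMethod("show", "TFARankTable", function(object) {
  cat(sprintf("TFARankTable: %d TFs x %d samples, %s%s\n",
              nrow(object@ranks), ncol(object@ranks), object@direction,
              if (object@standardized) " (standardized activities)" else ""))
})
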