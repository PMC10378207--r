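#' Accessors for flowMER data classes
#'
#' Slot accessors: flow components (`flowU`, `flowV`), strain magnitude
#' (`strainMagnitude`), triplet array (`tripletArray`), sequence frames and
#' indices, model/report pieces.
#'
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("flowU", function(x) standardGeneric("flowU"))
#' @rdname accessors
#' @export
setGeneric("flowV", function(x) standardGeneric("flowV"))
#' @rdname accessors
#' @export
setGeneric("strainMagnitude", function(x) standardGeneric("strainMagnitude"))
#' @rdname accessors
#' @export
setGeneric("tripletArray", function(x) standardGeneric("tripletArray"))
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("apexIndex", function(x) standardGeneric("apexIndex"))
#' @rdname accessors
#' @export
setGeneric("onsetIndex", function(x) standardGeneric("onsetIndex"))
#' @rdname accessors
#' @export
setGeneric("offsetIndex", function(x) standardGeneric("offsetIndex"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setGeneric("pooledAccuracy", function(x) standardGeneric("pooledAccuracy"))
#' @rdname accessors
#' @export
setGeneric("uf1", function(x) standardGeneric("uf1"))
#' @rdname accessors
#' @export
setGeneric("uar", function(x) standardGeneric("uar"))
#' @rdname accessors
#' @export
setGeneric("netConfig", function(x) standardGeneric("netConfig"))

#' @rdname accessors
#' @export
setMethod("flowU", "FlowField", function(x) x@u)
#' @rdname accessors
#' @export
setMethod("flowV", "FlowField", function(x) x@v)
#' @rdname accessors
#' @export
setMethod("strainMagnitude", "StrainMap", function(x) x@os)
#' @rdname accessors
#' @export
setMethod("tripletArray", "FlowTriplet", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("subjectId", "FrameSequence", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("apexIndex", "FrameSequence", function(x) x@apexIdx)
#' @rdname accessors
#' @export
setMethod("onsetIndex", "FrameSequence", function(x) x@onsetIdx)
#' @rdname accessors
#' @export
setMethod("offsetIndex", "FrameSequence", function(x) x@offsetIdx)
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)
#' @rdname accessors
#' @export
setMethod("pooledAccuracy", "EvalReport", function(x) x@accuracy)
#' @rdname accessors
#' @export
setMethod("uf1", "EvalReport", function(x) x@uf1)
#' @rdname accessors
#' @export
setMethod("uar", "EvalReport", function(x) x@uar)
#' @rdname accessors
#' @export
setMethod("netConfig", "FlowNetModel", function(x) x@config)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("FrameSequence: %d frames of %dx%d, subject '%s'\n",
              length(object@frames), d[1L], d[2L], object@subjectId))
  cat(sprintf("  onset %d, apex %s, offset %d\n", object@onsetIdx,
              ifelse(is.na(object@apexIdx), "<unset>", object@apexIdx),
              object@offsetIdx))
})

setMethod("show", "FlowField", function(object) {
  d <- dim(object@u)
  cat(sprintf("FlowField %dx%d: |u| max %.3g, |v| max %.3g px\n",
              d[1L], d[2L], max(abs(object@u)), max(abs(object@v))))
})

setMethod("show", "FlowTriplet", function(object) {
  d <- dim(object@data)
  cat(sprintf("FlowTriplet %dx%dx3 (u, v, os), range [%.3f, %.3f]\n",
              d[1L], d[2L], min(object@data), max(object@data)))
})

setMethod("show", "FlowNetModel", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("FlowNetModel: %d classes, %d parameters in %d tensors\n",
              object@config@nClasses, np, length(object@params)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d folds, %d samples, %d classes\n",
              length(object@folds), sum(object@confusion),
              nrow(object@confusion)))
  cat(sprintf("  pooled Acc %.4f | mean fold Acc %.4f | UF1 %.4f | UAR %.4f\n",
              object@accuracy, object@meanFoldAccuracy, object@uf1, object@uar))
})
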