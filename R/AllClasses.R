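#' @useDynLib flowMER, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Ordered micro-expression frame sequence
#'
#' Holds the grayscale frames of one micro-expression clip together with its
#' subject identifier and the 1-based onset/apex/offset frame indices. The
#' apex index may be `NA` when unknown; [locateApex()] can then spot it from
#' the LBP difference signal.
#'
#' @slot frames list of numeric H x W matrices, all of one size, intensities
#'   on a common scale (either `[0, 1]` or `[0, 255]`).
#' @slot subjectId single character subject identifier.
#' @slot onsetIdx,apexIdx,offsetIdx integer frame indices (1-based);
#'   `onsetIdx <= apexIdx <= offsetIdx` when the apex is present.
#' @export
setClass("FrameSequence",
  representation(frames = "list", subjectId = "character",
                 onsetIdx = "integer", apexIdx = "integer",
                 offsetIdx = "integer"))

setValidity("FrameSequence", function(object) {
  f <- object@frames
  if (length(f) < 2L) return("need at least 2 frames")
  if (!all(vapply(f, is.matrix, logical(1)))) return("frames must be matrices")
  d <- dim(f[[1L]])
  if (!all(vapply(f, function(m) identical(dim(m), d), logical(1))))
    return("all frames must share one shape")
  if (!all(vapply(f, function(m) all(is.finite(m)), logical(1))))
    return("frames must be finite")
  if (length(object@subjectId) != 1L) return("subjectId must be length 1")
  on <- object@onsetIdx; ap <- object@apexIdx; off <- object@offsetIdx
  if (is.na(on) || is.na(off)) return("onsetIdx/offsetIdx must be set")
  if (on < 1L || off > length(f) || on > off)
    return("need 1 <= onsetIdx <= offsetIdx <= length(frames)")
  if (!is.na(ap) && (ap < on || ap > off))
    return("need onsetIdx <= apexIdx <= offsetIdx")
  TRUE
})

#' @param frames,subjectId,onsetIdx,apexIdx,offsetIdx see slots.
#' @rdname FrameSequence-class
#' @export
FrameSequence <- function(frames, subjectId = "s1", onsetIdx = 1L,
                          apexIdx = NA_integer_, offsetIdx = length(frames)) {
  new("FrameSequence", frames = frames, subjectId = as.character(subjectId),
      onsetIdx = as.integer(onsetIdx), apexIdx = as.integer(apexIdx),
      offsetIdx = as.integer(offsetIdx))
}

#' Dense optical-flow field
#'
#' Per-pixel displacement between an onset and an apex frame. `u` is the
#' horizontal component (+x rightward, along columns) and `v` the vertical
#' component (+y downward, along rows), both in pixels per frame pair.
#'
#' @slot u,v numeric H x W matrices of identical shape, finite.
#' @export
setClass("FlowField", representation(u = "matrix", v = "matrix"))

setValidity("FlowField", function(object) {
  if (!identical(dim(object@u), dim(object@v))) return("u and v must share shape")
  if (!all(is.finite(object@u)) || !all(is.finite(object@v)))
    return("flow must be finite")
  TRUE
})

#' @param u,v displacement matrices, see slots.
#' @rdname FlowField-class
#' @export
FlowField <- function(u, v) new("FlowField", u = u, v = v)

#' Optical-strain magnitude map
#'
#' Scalar magnitude of the symmetric gradient (infinitesimal strain tensor)
#' of a flow field; non-negative, dimensionless, highlights fine local
#' deformation while ignoring rigid translation.
#'
#' @slot os numeric H x W matrix, finite and non-negative.
#' @export
setClass("StrainMap", representation(os = "matrix"))

setValidity("StrainMap", function(object) {
  if (!all(is.finite(object@os))) return("strain must be finite")
  if (any(object@os < 0)) return("strain must be non-negative")
  TRUE
})

#' @param os strain magnitude matrix.
#' @rdname StrainMap-class
#' @export
StrainMap <- function(os) new("StrainMap", os = os)

#' Normalized three-channel flow input
#'
#' The network input for one sample: channels (u, v, os), each min-max
#' normalized to `[0, 1]` and resized to `size x size` (28 by default).
#'
#' @slot data numeric array of dim `c(S, S, 3)` with values in `[0, 1]`.
#' @export
setClass("FlowTriplet", representation(data = "array"))

setValidity("FlowTriplet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[3L] != 3L) return("data must be S x S x 3")
  if (!all(is.finite(object@data))) return("triplet must be finite")
  if (min(object@data) < -1e-9 || max(object@data) > 1 + 1e-9)
    return("triplet values must lie in [0, 1]")
  TRUE
})

#' @param data array `c(S, S, 3)`.
#' @rdname FlowTriplet-class
#' @export
FlowTriplet <- function(data) new("FlowTriplet", data = data)

#' Network architecture configuration
#'
#' @slot nClasses number of emotion classes (>= 2).
#' @slot inputSize triplet side length; the channel arithmetic below assumes 28.
#' @slot kernelsBlock1,kernelsBlock2 convolution kernels per inception scale
#'   in the first (6) and second (16) block.
#' @slot samKernel odd kernel size of the spatial-attention convolution.
#' @slot camReduction squeeze-excitation reduction ratio of the shared
#'   channel-attention module.
#' @slot seed integer seed for weight initialization.
#' @export
setClass("NetConfig",
  representation(nClasses = "integer", inputSize = "integer",
                 kernelsBlock1 = "integer", kernelsBlock2 = "integer",
                 samKernel = "integer", camReduction = "integer",
                 seed = "integer"))

setValidity("NetConfig", function(object) {
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (object@kernelsBlock1 < 1L || object@kernelsBlock2 < 1L)
    return("kernels per scale must be >= 1")
  if (object@samKernel %% 2L == 0L) return("samKernel must be odd")
  if (object@inputSize %% 4L != 0L)
    return("inputSize must be divisible by 4 (two 2x2 poolings)")
  TRUE
})

#' @param nClasses,inputSize,kernelsBlock1,kernelsBlock2,samKernel,camReduction,seed
#'   see slots.
#' @rdname NetConfig-class
#' @export
NetConfig <- function(nClasses, inputSize = 28L, kernelsBlock1 = 6L,
                      kernelsBlock2 = 16L, samKernel = 7L, camReduction = 4L,
                      seed = 42L) {
  new("NetConfig", nClasses = as.integer(nClasses),
      inputSize = as.integer(inputSize),
      kernelsBlock1 = as.integer(kernelsBlock1),
      kernelsBlock2 = as.integer(kernelsBlock2),
      samKernel = as.integer(samKernel),
      camReduction = as.integer(camReduction), seed = as.integer(seed))
}

#' Training configuration
#'
#' Defaults follow the training recipe the method was published with: Adam,
#' learning rate 1e-4, weight decay 1e-4, batch size 8, 70 epochs, with
#' horizontal-flip and channel-dither augmentation.
#'
#' @slot lr,weightDecay,batchSize,epochs optimizer hyperparameters.
#' @slot seed integer; one seed governs initialization, shuffling and
#'   augmentation.
#' @slot augment logical, enable flip/dither augmentation.
#' @slot loss one of `"lasce"`, `"ce"`, `"focal"`, `"la_focal"`.
#' @slot tau logit-adjustment strength (0.5 by default); `tau = 0` makes
#'   LASCE coincide with plain cross-entropy.
#' @slot gamma focal-loss focusing parameter.
#' @slot eps additive guard inside the correction-factor logarithm.
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", weightDecay = "numeric",
                 batchSize = "integer", epochs = "integer", seed = "integer",
                 augment = "logical", loss = "character", tau = "numeric",
                 gamma = "numeric", eps = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@lr <= 0 || object@batchSize < 1L || object@epochs < 1L)
    return("hyperparameters must be positive")
  if (object@weightDecay < 0) return("weightDecay must be >= 0")
  if (!object@loss %in% c("ce", "focal", "lasce", "la_focal"))
    return("loss must be one of ce, focal, lasce, la_focal")
  if (object@tau < 0) return("tau must be >= 0")
  if (object@gamma < 0) return("gamma must be >= 0")
  if (object@eps <= 0) return("eps must be > 0")
  TRUE
})

#' @param lr,weightDecay,batchSize,epochs,seed,augment,loss,tau,gamma,eps
#'   see slots.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(lr = 1e-4, weightDecay = 1e-4, batchSize = 8L,
                        epochs = 70L, seed = 42L, augment = TRUE,
                        loss = "lasce", tau = 0.5, gamma = 2,
                        eps = 1e-12) {
  new("TrainConfig", lr = lr, weightDecay = weightDecay,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), augment = augment, loss = loss, tau = tau,
      gamma = gamma, eps = eps)
}

#' Trained (or initialized) three-branch flow network
#'
#' @slot params named list of weight arrays (flat, path-named keys).
#' @slot config the [NetConfig-class] the weights were built for.
#' @export
setClass("FlowNetModel",
  representation(params = "list", config = "NetConfig"))

#' Synthetic micro-motion dataset specification
#'
#' Describes the generative model of the bundled benchmark: localized
#' Gaussian displacement bumps at class-specific facial loci, a per-subject
#' random affine flow perturbation, i.i.d. flow noise, and a tent-shaped
#' temporal ramp peaking at the apex frame.
#'
#' @slot nClasses number of classes; every class in `1:nClasses` must own
#'   at least one row of `motionLoci`.
#' @slot motionLoci data.frame of displacement bumps with columns `class`,
#'   `name`, `row`, `col`, `radius` (fractions of the image), `dirX`,
#'   `dirY` (displacement direction, x right / y down).
#' @slot amplitude peak displacement in pixels.
#' @slot nSubjects number of subjects; samples are dealt round-robin.
#' @slot samplesPerClass integer vector, one entry per class (enables
#'   imbalance).
#' @slot subjectEffectSd SD (px) of the subject-level random affine flow.
#' @slot noiseSd SD (px) of i.i.d. per-pixel flow noise.
#' @slot seqLen,apexFrac frame count and fractional apex position of
#'   generated sequences.
#' @slot imageSize `c(H, W)` of generated rasters.
#' @slot tripletSize side length of derived triplets.
#' @slot seed master seed; everything is reproducible from it.
#' @export
setClass("SyntheticSpec",
  representation(nClasses = "integer", motionLoci = "data.frame",
                 amplitude = "numeric", nSubjects = "integer",
                 samplesPerClass = "integer", subjectEffectSd = "numeric",
                 noiseSd = "numeric", seqLen = "integer", apexFrac = "numeric",
                 imageSize = "integer", tripletSize = "integer",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  need <- c("class", "name", "row", "col", "radius", "dirX", "dirY")
  if (!all(need %in% names(object@motionLoci)))
    return("motionLoci needs columns class, name, row, col, radius, dirX, dirY")
  if (!all(seq_len(object@nClasses) %in% object@motionLoci$class))
    return("every class needs at least one motion locus")
  if (any(object@motionLoci$radius <= 0) || any(object@motionLoci$radius > 0.5))
    return("locus radius fraction must lie in (0, 0.5]")
  if (object@amplitude < 0) return("amplitude must be >= 0")
  if (length(object@samplesPerClass) != object@nClasses)
    return("samplesPerClass must have one entry per class")
  if (sum(object@samplesPerClass) < object@nSubjects)
    return("need at least one sample per subject")
  if (object@apexFrac <= 0 || object@apexFrac >= 1)
    return("apexFrac must lie in (0, 1)")
  if (object@seqLen < 5L) return("seqLen must be >= 5")
  TRUE
})

#' Canonical facial motion patterns
#'
#' Five action-unit-like motion patterns, each a set of Gaussian
#' displacement bumps (rows of the table; a class may own several loci).
#' Classes differ in motion *direction* composition, not merely in bump
#' position — mimicking how facial action units differ by which muscles
#' contract which way, and matching the translation-invariance of a
#' global-average-pooled classifier. Every pattern is invariant under
#' horizontal mirroring (bilateral pairs or midline loci), the symmetry the
#' flip augmentation of the training recipe presumes.
#'
#' Patterns: (1) jawDrop — midline downward mouth/chin motion;
#' (2) browRaise — bilateral upward brow motion; (3) noseWrinkle —
#' convergent vertical pinch at the nose root (opposing up/down lobes);
#' (4) smilePull — mouth corners drawn outward and up; (5) lipPress —
#' mouth corners drawn inward and down. The first three differ in the sign
#' composition of vertical motion, the last two add lateral structure.
#'
#' @return data.frame with columns class, name, row, col, radius, dirX,
#'   dirY (direction need not be unit length; it is normalized per locus).
#' @export
defaultMotionLoci <- function() {
  data.frame(
    class  = c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L),
    name   = c("jawDrop", "browRaise", "browRaise", "noseWrinkle",
               "noseWrinkle", "smilePull", "smilePull", "lipPress",
               "lipPress"),
    row    = c(0.82, 0.22, 0.22, 0.38, 0.20, 0.75, 0.75, 0.75, 0.75),
    col    = c(0.50, 0.35, 0.65, 0.50, 0.50, 0.30, 0.70, 0.30, 0.70),
    radius = c(0.12, 0.10, 0.10, 0.09, 0.08, 0.10, 0.10, 0.09, 0.09),
    dirX   = c(0, 0, 0, 0, 0, -0.7, 0.7, 0.7, -0.7),
    dirY   = c(1, -1, -1, -1, 1, -0.7, -0.7, 0.7, 0.7))
}

#' @param nClasses,motionLoci,amplitude,nSubjects,samplesPerClass,subjectEffectSd,noiseSd,seqLen,apexFrac,imageSize,tripletSize,seed
#'   see slots.
#' @rdname SyntheticSpec-class
#' @export
SyntheticSpec <- function(nClasses = 3L, motionLoci = defaultMotionLoci(),
                          amplitude = 2, nSubjects = 10L,
                          samplesPerClass = rep(30L, nClasses),
                          subjectEffectSd = 0.2, noiseSd = 0.1,
                          seqLen = 20L, apexFrac = 0.6,
                          imageSize = c(64L, 64L), tripletSize = 28L,
                          seed = 42L) {
  new("SyntheticSpec", nClasses = as.integer(nClasses),
      motionLoci = motionLoci, amplitude = amplitude,
      nSubjects = as.integer(nSubjects),
      samplesPerClass = as.integer(samplesPerClass),
      subjectEffectSd = subjectEffectSd, noiseSd = noiseSd,
      seqLen = as.integer(seqLen), apexFrac = apexFrac,
      imageSize = as.integer(imageSize), tripletSize = as.integer(tripletSize),
      seed = as.integer(seed))
}

#' Leave-one-subject-out evaluation report
#'
#' @slot confusion pooled C x C confusion matrix, rows = truth.
#' @slot perClass data.frame with per-class TP/FP/FN, accuracy (recall) and
#'   F1.
#' @slot accuracy pooled accuracy (trace / total).
#' @slot meanFoldAccuracy mean of per-fold accuracies.
#' @slot uf1,uar macro-averaged F1 and recall.
#' @slot folds per-fold records (subject, n, accuracy, loss history).
#' @slot predictions per-sample data.frame (sampleId, subjectId, truth,
#'   predicted).
#' @slot labelVocab ordered class names.
#' @slot seed seed the run was launched with.
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 accuracy = "numeric", meanFoldAccuracy = "numeric",
                 uf1 = "numeric", uar = "numeric", folds = "list",
                 predictions = "data.frame", labelVocab = "character",
                 seed = "integer"))

setValidity("EvalReport", function(object) {
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) return("confusion must be square")
  if (any(cm < 0)) return("confusion entries must be >= 0")
  if (length(object@uf1) && (object@uf1 < 0 || object@uf1 > 1))
    return("UF1 must lie in [0, 1]")
  if (length(object@uar) && (object@uar < 0 || object@uar > 1))
    return("UAR must lie in [0, 1]")
  TRUE
})
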