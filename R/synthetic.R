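# Synthetic micro-motion benchmark: localized Gaussian displacement bumps
# at class-specific facial loci, subject-level random affine flow, i.i.d.
# flow noise, and tent-ramp frame sequences for apex spotting. Everything
# derives from one seed.

.classFlow <- function(spec, class) {
  H <- spec@imageSize[1L]; W <- spec@imageSize[2L]
  loci <- spec@motionLoci[spec@motionLoci$class == class, , drop = FALSE]
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  u <- matrix(0, H, W); v <- matrix(0, H, W)
  for (q in seq_len(nrow(loci))) {
    loc <- loci[q, ]
    cx <- loc$col * (W - 1) + 1; cy <- loc$row * (H - 1) + 1
    sg <- loc$radius * min(H, W)
    g <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sg^2))
    nrm <- sqrt(loc$dirX^2 + loc$dirY^2)
    u <- u + spec@amplitude * loc$dirX / nrm * g
    v <- v + spec@amplitude * loc$dirY / nrm * g
  }
  list(u = u, v = v)
}

.subjectAffine <- function(spec) {
  # 6 coefficients per subject: u += a1 xn + a2 yn + a3 (xn, yn in [-.5, .5])
  matrix(stats::rnorm(spec@nSubjects * 6L, sd = spec@subjectEffectSd),
         spec@nSubjects, 6L)
}

#' Generate one synthetic flow sample
#'
#' Ground-truth flow = class bump + subject affine perturbation + i.i.d.
#' Gaussian noise; the triplet is derived through the package's own strain
#' and normalization chain, exactly as real data would be.
#'
#' @param spec a [SyntheticSpec-class].
#' @param class 1-based class index.
#' @param subjectEffect length-6 affine coefficient vector (zeros for
#'   none), as drawn by [makeDataset()] per subject.
#' @return list with `flow` ([FlowField-class] ground truth) and `triplet`
#'   ([FlowTriplet-class]). Uses the current RNG stream for the noise.
#' @export
makeFlowSample <- function(spec, class, subjectEffect = numeric(6L)) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (class < 1L || class > spec@nClasses) stop("invalid class index")
  H <- spec@imageSize[1L]; W <- spec@imageSize[2L]
  fl <- .classFlow(spec, class)
  xn <- matrix(seq_len(W) / W - 0.5, H, W, byrow = TRUE)
  yn <- matrix(seq_len(H) / H - 0.5, H, W)
  u <- fl$u + subjectEffect[1L] * xn + subjectEffect[2L] * yn + subjectEffect[3L]
  v <- fl$v + subjectEffect[4L] * xn + subjectEffect[5L] * yn + subjectEffect[6L]
  if (spec@noiseSd > 0) {
    u <- u + matrix(stats::rnorm(H * W, sd = spec@noiseSd), H, W)
    v <- v + matrix(stats::rnorm(H * W, sd = spec@noiseSd), H, W)
  }
  flow <- FlowField(u, v)
  list(flow = flow,
       triplet = flowToTriplet(flow, opticalStrain(flow), spec@tripletSize))
}

#' Generate a synthetic frame sequence with a known apex
#'
#' A smooth random texture (Gaussian-filtered white noise, filter sigma
#' 2 px) is warped frame-by-frame by the class flow scaled with a tent ramp
#' that rises from the onset to the apex and falls to the offset, using
#' inverse bilinear sampling with replicated borders. The true apex index
#' `round(apexFrac * (seqLen - 1)) + 1` is recorded on the returned
#' sequence.
#'
#' @inheritParams makeFlowSample
#' @param subject subject identifier string.
#' @return a [FrameSequence-class] whose `apexIdx` is the ground truth.
#' @export
makeSequence <- function(spec, class, subject = "s1",
                         subjectEffect = numeric(6L)) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (class < 1L || class > spec@nClasses) stop("invalid class index")
  H <- spec@imageSize[1L]; W <- spec@imageSize[2L]
  tex <- minMaxNormalize(gauss_blur(matrix(stats::rnorm(H * W), H, W), 2))
  fl <- .classFlow(spec, class)
  xn <- matrix(seq_len(W) / W - 0.5, H, W, byrow = TRUE)
  yn <- matrix(seq_len(H) / H - 0.5, H, W)
  u <- fl$u + subjectEffect[1L] * xn + subjectEffect[2L] * yn + subjectEffect[3L]
  v <- fl$v + subjectEffect[4L] * xn + subjectEffect[5L] * yn + subjectEffect[6L]
  Tn <- spec@seqLen
  apex0 <- round(spec@apexFrac * (Tn - 1))       # 0-based
  ramp <- vapply(0:(Tn - 1), function(t) {
    if (t <= apex0) t / max(apex0, 1) else (Tn - 1 - t) / max(Tn - 1 - apex0, 1)
  }, numeric(1))
  framesL <- lapply(seq_len(Tn), function(i) {
    r <- ramp[i]
    if (r == 0) tex else bilinear_warp(tex, -r * u, -r * v)
  })
  FrameSequence(framesL, subjectId = subject, onsetIdx = 1L,
                apexIdx = as.integer(apex0 + 1L), offsetIdx = Tn)
}

#' Generate the full synthetic triplet dataset
#'
#' Class counts follow `samplesPerClass` exactly; samples are dealt to
#' subjects round-robin across the concatenated class blocks, and subject
#' affine effects are drawn once per subject. Fully reproducible from
#' `spec@seed` (the session RNG is left untouched).
#'
#' @param spec a [SyntheticSpec-class].
#' @return dataset list: `triplets` (S x S x 3 x N), `labels`, `subjects`,
#'   `sampleIds`, `labelVocab`, `manifest` data.frame, `trueFlows` (list of
#'   ground-truth [FlowField-class]s), `loci` (per-sample class locus rows),
#'   and the generating `spec`.
#' @export
makeDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  N <- sum(spec@samplesPerClass)
  if (N < spec@nSubjects) stop("fewer samples than subjects")
  oldseed <- .Random.seed_save()
  on.exit(.Random.seed_restore(oldseed))
  set.seed(spec@seed)
  eff <- .subjectAffine(spec)
  S <- spec@tripletSize
  tri <- array(0, c(S, S, 3L, N))
  labels <- integer(N); subjects <- character(N); ids <- character(N)
  flows <- vector("list", N)
  i <- 0L
  for (k in seq_len(spec@nClasses)) {
    for (j in seq_len(spec@samplesPerClass[k])) {
      i <- i + 1L
      sj <- ((i - 1L) %% spec@nSubjects) + 1L
      smp <- makeFlowSample(spec, k, eff[sj, ])
      tri[, , , i] <- smp$triplet@data
      labels[i] <- k
      subjects[i] <- sprintf("subj%02d", sj)
      ids[i] <- sprintf("c%d_n%03d", k, j)
      flows[[i]] <- smp$flow
    }
  }
  vocab <- vapply(seq_len(spec@nClasses), function(k) {
    nm <- unique(spec@motionLoci$name[spec@motionLoci$class == k])
    if (length(nm)) nm[1L] else paste0("class", k)
  }, character(1))
  list(triplets = tri, labels = labels, subjects = subjects, sampleIds = ids,
       labelVocab = vocab,
       manifest = data.frame(sample_id = ids, subject_id = subjects,
                             label = vocab[labels], stringsAsFactors = FALSE),
       trueFlows = flows, spec = spec)
}
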