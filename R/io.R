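#' Read a dataset manifest CSV
#'
#' Required columns: `sample_id`, `subject_id`, `frames_dir`, `onset`,
#' `apex`, `offset`, `label`. Frame indices are 1-based; a blank/NA `apex`
#' marks the sample for apex spotting. The label vocabulary is the order of
#' first appearance and is recorded explicitly (argmax tie-breaks depend on
#' it).
#'
#' @param path CSV file path.
#' @return list with `records` (data.frame incl. integer `labelIdx`) and
#'   `labelVocab`.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "frames_dir", "onset", "apex",
            "offset", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  df$apex <- suppressWarnings(as.integer(df$apex))   # blank -> NA
  df$onset <- as.integer(df$onset); df$offset <- as.integer(df$offset)
  vocab <- unique(df$label)
  df$labelIdx <- match(df$label, vocab)
  list(records = df, labelVocab = vocab)
}

#' Write a dataset manifest CSV
#'
#' @param manifest list as returned by [readManifest()] (or a compatible
#'   data.frame in `records`).
#' @param path output CSV path.
#' @export
writeManifest <- function(manifest, path) {
  df <- manifest$records
  df$labelIdx <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a frame directory as a FrameSequence
#'
#' Frames are read in lexicographic filename order via EBImage (PNG/JPG/
#' BMP/TIFF); color frames are averaged to grayscale.
#'
#' @param framesDir directory of image frames.
#' @param subjectId,onsetIdx,apexIdx,offsetIdx sequence metadata (1-based).
#' @return a [FrameSequence-class].
#' @export
readFrameSequence <- function(framesDir, subjectId = "s1", onsetIdx = 1L,
                              apexIdx = NA_integer_, offsetIdx = NULL) {
  files <- sort(list.files(framesDir, full.names = TRUE,
                           pattern = "\\.(png|jpg|jpeg|bmp|tif|tiff)$",
                           ignore.case = TRUE))
  if (length(files) < 2L) stop("need at least 2 frames in ", framesDir)
  framesL <- lapply(files, function(f) {
    img <- EBImage::imageData(EBImage::readImage(f))
    if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
    # EBImage stores x-y; transpose to row = y convention
    t(img)
  })
  if (is.null(offsetIdx)) offsetIdx <- length(framesL)
  FrameSequence(framesL, subjectId = subjectId, onsetIdx = onsetIdx,
                apexIdx = apexIdx, offsetIdx = offsetIdx)
}

#' Preprocess every manifest entry into a triplet dataset
#'
#' @param manifest list from [readManifest()].
#' @param baseDir directory frame paths are relative to.
#' @param size triplet side length.
#' @param params flow-solver settings.
#' @return dataset list compatible with [evaluateLoso()].
#' @export
preprocessManifest <- function(manifest, baseDir = ".", size = 28L,
                               params = flowParams()) {
  rec <- manifest$records
  N <- nrow(rec)
  tri <- array(0, c(size, size, 3L, N))
  for (i in seq_len(N)) {
    seq <- readFrameSequence(file.path(baseDir, rec$frames_dir[i]),
                             subjectId = rec$subject_id[i],
                             onsetIdx = rec$onset[i], apexIdx = rec$apex[i],
                             offsetIdx = rec$offset[i])
    tri[, , , i] <- preprocessSample(seq, size = size, params = params)@data
  }
  list(triplets = tri, labels = rec$labelIdx, subjects = rec$subject_id,
       sampleIds = rec$sample_id, labelVocab = manifest$labelVocab)
}

#' Write / read a triplet dataset archive
#'
#' Serialized as RDS with a metadata stamp (normalization rule, package
#' version, creation fields); byte-identical for identical inputs.
#'
#' @param dataset dataset list ([makeDataset()]/[preprocessManifest()]).
#' @param path archive path (conventionally `.rds`).
#' @export
writeTripletArchive <- function(dataset, path) {
  dataset$metadata <- list(normalization = "per-sample per-channel min-max",
                           package = "flowMER",
                           version = as.character(utils::packageVersion("flowMER")))
  saveRDS(dataset, path, version = 3L)
  invisible(path)
}

#' @rdname writeTripletArchive
#' @return `readTripletArchive` returns the dataset list.
#' @export
readTripletArchive <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  readRDS(path)
}

#' Export an evaluation report as JSON
#'
#' Confusion matrix (integer), per-class table, pooled and macro metrics,
#' label vocabulary and seed; [readReport()] restores the numbers exactly.
#'
#' @param report an [EvalReport-class].
#' @param path output JSON path.
#' @export
exportReport <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  obj <- list(
    confusion = unname(apply(report@confusion, 2L, as.integer)),
    labelVocab = report@labelVocab,
    perClass = report@perClass,
    accuracy = report@accuracy,
    meanFoldAccuracy = report@meanFoldAccuracy,
    uf1 = report@uf1, uar = report@uar,
    folds = lapply(report@folds, function(f)
      list(subject = f$subject, n = f$n, accuracy = f$accuracy)),
    seed = report@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname exportReport
#' @return `readReport` returns the parsed report list.
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a Grad-CAM heatmap as an 8-bit PNG
#'
#' Grayscale by default; with `overlay` (typically the u channel of the
#' triplet) a fixed red-heat blend over the base image is written.
#'
#' @param heatmap matrix in `[0, 1]`.
#' @param path output PNG path.
#' @param overlay optional base matrix in `[0, 1]` of the same shape.
#' @export
exportHeatmap <- function(heatmap, path, overlay = NULL) {
  stopifnot(is.matrix(heatmap), min(heatmap) >= 0, max(heatmap) <= 1)
  if (is.null(overlay)) {
    img <- EBImage::Image(t(heatmap))
  } else {
    stopifnot(identical(dim(overlay), dim(heatmap)))
    r <- 0.35 * overlay + 0.85 * heatmap
    r[r > 1] <- 1
    g <- 0.35 * overlay + 0.25 * heatmap
    b <- 0.35 * overlay * (1 - heatmap)
    img <- EBImage::Image(array(c(t(r), t(g), t(b)),
                                dim = c(ncol(r), nrow(r), 3L)),
                          colormode = "Color")
  }
  EBImage::writeImage(img, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Merge run configuration for serialization
#'
#' Flattens the network/training configurations plus free-form paths into a
#' YAML-ready list that round-trips losslessly through [writeRunConfig()] /
#' [readRunConfig()].
#'
#' @param netConfig a [NetConfig-class].
#' @param trainConfig a [TrainConfig-class].
#' @param ... additional scalar fields (paths etc.).
#' @return named list.
#' @export
runConfig <- function(netConfig, trainConfig, ...) {
  nc <- attributes(netConfig); tc <- attributes(trainConfig)
  nc$class <- NULL; tc$class <- NULL
  list(net = nc, train = tc, extra = list(...),
       package = as.character(utils::packageVersion("flowMER")))
}

#' @rdname runConfig
#' @param cfg list from [runConfig()].
#' @param path YAML file path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname runConfig
#' @return `readRunConfig` returns the configuration list; `asNetConfig` /
#'   `asTrainConfig` rebuild the S4 objects.
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname runConfig
#' @export
asNetConfig <- function(cfg) do.call(NetConfig, cfg$net)

#' @rdname runConfig
#' @export
asTrainConfig <- function(cfg) do.call(TrainConfig, cfg$train)
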