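# Assembly of the full per-image feature vector and dataset-level
# feature tables.

#' Extract the full feature vector of one ROI
#'
#' Concatenates, in a frozen order, the four feature families:
#' multiresolution LBP on the raw red channel, the illumination-normalised
#' green channel and the raw blue channel (2006 each); RGB and L*a*b*
#' colour histograms (48 + 48); HOG (3600); and, when a vocabulary is
#' supplied, the bag-of-visual-words histogram (K).
#'
#' @param roi an `roi_image`.
#' @param vocab optional `surf_vocabulary`; if supplied, `keypoints`
#'   (or a fresh detection) is histogrammed into K extra features.
#' @param keypoints optional precomputed [detect_keypoints()] matrix.
#' @param wavelet,mode passed to [wavelet_decompose()].
#' @param color_bins bins per colour channel (default 16).
#' @return an object of class `feature_vector`: a named numeric vector
#'   with a `groups` attribute tagging each feature with one of
#'   `LBP_red`, `LBP_green`, `LBP_blue`, `RGB_hist`, `Lab_hist`, `HOG`,
#'   `SURF`.
#' @export
extract_features <- function(roi, vocab = NULL, keypoints = NULL,
                             wavelet = "bl24", mode = "symmetric",
                             color_bins = 16) {
  stopifnot(inherits(roi, "roi_image"))
  chans <- list(LBP_red = roi$pixels[, , 1],
                LBP_green = roi$green_norm,
                LBP_blue = roi$pixels[, , 3])
  lbp <- lapply(names(chans), function(nm) {
    v <- lbp_features(wavelet_decompose(chans[[nm]], wavelet, mode))
    names(v) <- paste0(sub("LBP_", "lbp_", nm), "_", names(v))
    v
  })
  col <- color_histograms(roi, bins = color_bins)
  hog <- hog_features(roi)
  vals <- c(lbp[[1]], lbp[[2]], lbp[[3]], col, hog)
  groups <- c(rep(c("LBP_red", "LBP_green", "LBP_blue"),
                  each = length(lbp[[1]])),
              rep(c("RGB_hist", "Lab_hist"), each = length(col) / 2),
              rep("HOG", length(hog)))
  if (!is.null(vocab)) {
    if (is.null(keypoints)) keypoints <- detect_keypoints(roi)
    sv <- surf_features(keypoints, vocab)
    vals <- c(vals, sv)
    groups <- c(groups, rep("SURF", length(sv)))
  }
  if (any(!is.finite(vals))) stop("non-finite feature values")
  structure(vals, groups = groups, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d features: %s\n", length(x),
              paste(sprintf("%s=%d", names(table(attr(x, "groups"))),
                            table(attr(x, "groups"))), collapse = ", ")))
  invisible(x)
}

#' Featurize a dataset
#'
#' Preprocesses every image (ROI + illumination normalisation), computes
#' the fold-independent features (LBP, colour, HOG) and detects keypoint
#' descriptors once per image.  Bag-of-visual-words features depend on
#' the training partition and are appended later by
#' [append_surf_features()] so that vocabularies can be rebuilt inside
#' each cross-validation fold.
#'
#' @param images list of `fundus_image` objects.
#' @param wavelet,mode,color_bins feature parameters.
#' @param surf_threshold Hessian response threshold for keypoints.
#' @param verbose print progress every 50 images.
#' @return an object of class `feature_set`: list with `X` (n x p
#'   matrix), `groups`, `keypoints` (list of descriptor matrices),
#'   `labels`, `quality`, `ids`.
#' @export
featurize_dataset <- function(images, wavelet = "bl24", mode = "symmetric",
                              color_bins = 16, surf_threshold = 600,
                              verbose = FALSE) {
  rois <- lapply(images, extract_roi)
  fv1 <- extract_features(rois[[1]], wavelet = wavelet, mode = mode,
                          color_bins = color_bins)
  X <- matrix(NA_real_, length(rois), length(fv1),
              dimnames = list(vapply(images, `[[`, "", "id"), names(fv1)))
  X[1, ] <- fv1
  kps <- vector("list", length(rois))
  kps[[1]] <- detect_keypoints(rois[[1]], threshold = surf_threshold)
  for (i in seq_along(rois)[-1]) {
    X[i, ] <- extract_features(rois[[i]], wavelet = wavelet, mode = mode,
                               color_bins = color_bins)
    kps[[i]] <- detect_keypoints(rois[[i]], threshold = surf_threshold)
    if (verbose && i %% 50 == 0) message("featurized ", i, " images")
  }
  structure(
    list(X = X, groups = attr(fv1, "groups"), keypoints = kps,
         labels = vapply(images, `[[`, NA_real_, "label"),
         quality = vapply(images, function(im)
           ifelse(is.na(im$quality), NA_character_, im$quality), ""),
         ids = vapply(images, `[[`, "", "id")),
    class = "feature_set")
}

#' Append bag-of-visual-words features for a given vocabulary
#'
#' @param fs a `feature_set`.
#' @param vocab a `surf_vocabulary` (built from training-partition
#'   keypoints only).
#' @return a `feature_set` whose `X` has K extra `SURF`-group columns.
#' @export
append_surf_features <- function(fs, vocab) {
  stopifnot(inherits(fs, "feature_set"))
  n_static <- sum(fs$groups != "SURF")  # SURF columns sit at the end
  fs$X <- fs$X[, seq_len(n_static), drop = FALSE]
  fs$groups <- fs$groups[fs$groups != "SURF"]
  S <- t(vapply(fs$keypoints, surf_features, numeric(vocab$K),
                vocab = vocab))
  colnames(S) <- paste0("surf_word", seq_len(vocab$K))
  fs$X <- cbind(fs$X, S)
  fs$groups <- c(fs$groups, rep("SURF", vocab$K))
  fs
}
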