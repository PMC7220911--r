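# Angular planes with exclusion masks, and automated specular-artifact
# detection.

#' Angular scattering plane with exclusion mask
#'
#' A 2D angular intensity distribution (theta_x by theta_y) plus a boolean
#' exclusion mask (`TRUE` = excluded from analysis) and record metadata.
#' Records retaining less than half of their pixels are flagged.
#'
#' @param intensity numeric matrix, finite.
#' @param mask logical matrix of the same shape (`TRUE` = excluded), or
#'   `NULL` for no exclusions.
#' @param layer,eye,location optional metadata tags.
#' @return object of class `angular_plane`.
#' @export
angular_plane <- function(intensity, mask = NULL, layer = NA_character_,
                          eye = NA_character_, location = NA_integer_) {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  stopifnot(is.logical(mask), all(dim(mask) == dim(intensity)))
  structure(
    list(intensity = intensity, mask = mask, layer = layer, eye = eye,
         location = location, flagged = mean(mask) > 0.5),
    class = "angular_plane"
  )
}

#' @export
print.angular_plane <- function(x, ...) {
  cat(sprintf("Angular plane %dx%d (%s), %.1f%% excluded%s\n",
              nrow(x$intensity), ncol(x$intensity),
              ifelse(is.na(x$layer), "untagged", x$layer),
              100 * mean(x$mask), if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

as_angular_plane <- function(x) {
  if (inherits(x, "angular_plane")) x else angular_plane(as.matrix(x))
}

#' Detect specular-reflection artifacts in an angular plane
#'
#' Automated analogue of manual artifact exclusion: pixels brighter than
#' `median + 6 * MAD` (robust against heavy-tailed speckle) are grouped into
#' connected components and dilated by 2 pixels to form the exclusion mask.
#' A user-supplied mask overrides detection entirely. Planes with more than
#' half their pixels excluded are flagged.
#'
#' @param plane an [angular_plane()] or numeric matrix (nonnegative).
#' @param user_mask optional explicit logical exclusion mask; returned
#'   unchanged when provided.
#' @param n_mad threshold multiplier on the MAD.
#' @param dilate_px dilation radius, pixels.
#' @return logical exclusion mask with attribute `flagged` (`TRUE` when more
#'   than 50\% of pixels are excluded).
#' @export
detect_specular <- function(plane, user_mask = NULL, n_mad = 6, dilate_px = 2) {
  p <- as_angular_plane(plane)
  x <- p$intensity
  stopifnot(all(x >= 0))
  if (!is.null(user_mask)) {
    stopifnot(is.logical(user_mask), all(dim(user_mask) == dim(x)))
    attr(user_mask, "flagged") <- mean(user_mask) > 0.5
    return(user_mask)
  }
  med <- stats::median(x)
  thr <- med + n_mad * stats::mad(x)
  hot <- x > thr
  if (any(hot) && dilate_px > 0) {
    brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
    hot <- EBImage::dilate(EBImage::Image(hot * 1), brush) > 0
    hot <- matrix(as.logical(hot), nrow(x), ncol(x))
  }
  attr(hot, "flagged") <- mean(hot) > 0.5
  hot
}

#' Apply an exclusion mask to an angular plane
#'
#' @param plane an [angular_plane()] or matrix.
#' @param mask logical exclusion mask.
#' @return the plane with the mask attached (metadata preserved).
#' @export
apply_mask <- function(plane, mask) {
  p <- as_angular_plane(plane)
  angular_plane(p$intensity, mask, layer = p$layer, eye = p$eye,
                location = p$location)
}
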