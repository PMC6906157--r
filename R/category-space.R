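#' Define a two-category Gabor stimulus space
#'
#' Gabor patches are characterized by spatial frequency (cycles per stimulus
#' width) and orientation (degrees, modulo 180). Two task variants partition
#' the feature space into two categories:
#' \describe{
#'   \item{II (information integration)}{a diagonal boundary in normalized
#'     feature coordinates, so the category depends on a joint (non
#'     verbalizable) combination of frequency and orientation. The sign of
#'     the boundary slope is counterbalanced across participants.}
#'   \item{RB (rule based)}{a conjunction rule with one vertical and one
#'     horizontal cut: category 1 stimuli are more vertical with lower
#'     frequency, or more horizontal with higher frequency (an exclusive-or
#'     over the two cuts); category 2 is the opposite pattern.}
#' }
#' Both variants admit a polarity flag that swaps the category-to-region
#' assignment (counterbalancing).
#'
#' Features are handled internally on the normalized unit square: frequency
#' mapped linearly from `freq_range` to `[0, 1]`, orientation from
#' `[0, 180)` degrees to `[0, 1)`. The II boundary is the main diagonal
#' (slope sign `"+"`) or the anti-diagonal (`"-"`); the RB cuts sit at the
#' domain midpoints. The published task does not print numeric feature
#' ranges or boundary coordinates, so these normalized defaults preserve the
#' topology (diagonal versus quadrant rule) without inventing units.
#'
#' @param task `"II"` or `"RB"`.
#' @param polarity `"A"` or `"B"`; `"B"` swaps all category labels.
#' @param slope_sign `"+"` or `"-"`; sign of the II diagonal boundary slope.
#' @param freq_range Length-2 numeric, the frequency domain in cycles per
#'   stimulus width (strictly positive).
#' @return An object of class `category_space`.
#' @export
#' @examples
#' sp <- category_space("RB")
#' assign_category(data.frame(frequency = 1.5, orientation = 120), sp)
category_space <- function(task = c("II", "RB"), polarity = c("A", "B"),
                           slope_sign = c("+", "-"),
                           freq_range = c(1, 4)) {
  task <- match.arg(task)
  polarity <- match.arg(polarity)
  slope_sign <- match.arg(slope_sign)
  if (length(freq_range) != 2L || any(freq_range <= 0) ||
      diff(freq_range) <= 0) {
    stop("`freq_range` must be an increasing positive pair", call. = FALSE)
  }
  structure(
    list(
      task = task, polarity = polarity,
      ii = list(slope_sign = slope_sign, intercept = 0, slope = 1),
      rb = list(freq_cut = 0.5, orient_cut = 0.5),
      freq_range = as.numeric(freq_range)
    ),
    class = "category_space"
  )
}

#' @export
print.category_space <- function(x, ...) {
  cat(sprintf(
    "<category_space> %s task, polarity %s%s; frequency domain [%g, %g] c/w\n",
    x$task, x$polarity,
    if (x$task == "II") paste0(", slope sign ", x$ii$slope_sign) else "",
    x$freq_range[1], x$freq_range[2]))
  invisible(x)
}

# Map physical features to the normalized unit square.
normalize_features <- function(space, frequency, orientation) {
  fx <- (frequency - space$freq_range[1]) / diff(space$freq_range)
  oy <- (orientation %% 180) / 180
  if (any(fx < 0 | fx > 1)) {
    stop("stimulus frequency outside the feature domain", call. = FALSE)
  }
  cbind(x = fx, y = oy)
}

# Signed boundary coordinate(s) on the normalized square. For II this is the
# signed distance-like residual to the diagonal; for RB the two cut offsets.
boundary_signs <- function(space, xy) {
  if (space$task == "II") {
    s <- if (space$ii$slope_sign == "+") {
      xy[, "y"] - (space$ii$intercept + space$ii$slope * xy[, "x"])
    } else {
      xy[, "y"] - (1 - space$ii$slope * xy[, "x"])
    }
    cbind(s)
  } else {
    cbind(xy[, "x"] - space$rb$freq_cut, xy[, "y"] - space$rb$orient_cut)
  }
}

#' Assign category labels to stimuli
#'
#' Deterministically labels each stimulus 1 or 2 according to the category
#' space. Stimuli lying exactly on a decision boundary are rejected, as are
#' stimuli outside the feature domain.
#'
#' @param stimuli Data frame with columns `frequency` and `orientation`.
#' @param space A [category_space()].
#' @return The input as a tibble with a `category` column (integer 1/2).
#' @export
assign_category <- function(stimuli, space) {
  stopifnot(inherits(space, "category_space"),
            all(c("frequency", "orientation") %in% names(stimuli)))
  if (any(stimuli$frequency <= 0)) {
    stop("frequency must be strictly positive", call. = FALSE)
  }
  xy <- normalize_features(space, stimuli$frequency, stimuli$orientation)
  s <- boundary_signs(space, xy)
  if (any(s == 0)) {
    stop("stimulus lies exactly on a decision boundary", call. = FALSE)
  }
  cat1 <- if (space$task == "II") {
    s[, 1] > 0
  } else {
    # conjunction rule: more vertical & lower frequency, or the opposite pair
    xor(s[, 2] > 0, s[, 1] > 0)
  }
  if (space$polarity == "B") cat1 <- !cat1
  out <- tibble::as_tibble(stimuli)
  out$category <- as.integer(unname(ifelse(cat1, 1L, 2L)))
  out
}

#' Sample a balanced stimulus list
#'
#' Draws `n` stimuli, exactly `n/2` per category, uniformly within each
#' category region of the normalized feature square, excluding a margin
#' around the decision boundaries so that no sampled stimulus is ambiguous
#' (category example clouds are well separated from the boundary).
#'
#' @param space A [category_space()].
#' @param n Even number of stimuli, at least 2.
#' @param rng_seed Integer seed; the same seed reproduces the same list.
#' @param margin Boundary exclusion margin in normalized units.
#' @return Tibble with columns `trial`, `frequency`, `orientation`,
#'   `category`.
#' @export
sample_stimuli <- function(space, n, rng_seed, margin = 0.02) {
  stopifnot(inherits(space, "category_space"))
  if (n < 2 || n %% 2 != 0) {
    stop("`n` must be an even number >= 2", call. = FALSE)
  }
  if (margin < 0 || margin >= 0.45) {
    stop("`margin` must be in [0, 0.45)", call. = FALSE)
  }
  per_cat <- n / 2
  draw_region <- function(target_cat, seed) {
    with_seed_(seed, {
      got_x <- numeric(0)
      got_y <- numeric(0)
      while (length(got_x) < per_cat) {
        m <- max(64L, 4L * (per_cat - length(got_x)))
        x <- stats::runif(m)
        y <- stats::runif(m)
        s <- boundary_signs(space, cbind(x = x, y = y))
        clear <- apply(abs(s) > margin, 1L, all)
        cat1 <- if (space$task == "II") s[, 1] > 0 else xor(s[, 2] > 0, s[, 1] > 0)
        if (space$polarity == "B") cat1 <- !cat1
        keep <- clear & (cat1 == (target_cat == 1L))
        got_x <- c(got_x, x[keep])
        got_y <- c(got_y, y[keep])
      }
      cbind(got_x[seq_len(per_cat)], got_y[seq_len(per_cat)])
    })
  }
  xy <- rbind(draw_region(1L, derive_seed(rng_seed, 1L)),
              draw_region(2L, derive_seed(rng_seed, 2L)))
  out <- tibble::tibble(
    frequency = space$freq_range[1] + xy[, 1] * diff(space$freq_range),
    orientation = xy[, 2] * 180,
    category = rep(c(1L, 2L), each = per_cat)
  )
  # interleave categories so trial order is not blocked
  out <- out[with_seed_(derive_seed(rng_seed, 3L), sample.int(n)), ]
  out$trial <- seq_len(n)
  out[, c("trial", "frequency", "orientation", "category")]
}
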