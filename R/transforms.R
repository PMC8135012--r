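# Age transformations linking chronological age to the clock regression
# response and back.

#' Construct an age transform
#'
#' An age transform maps chronological age (years) to the scale on which a
#' clock's penalized regression is fitted, and back. Three kinds are
#' supported:
#'
#' * `"identity"`: the response is chronological age in years. The default
#'   for within-species clocks.
#' * `"relative"`: the response is relative age, chronological age divided by
#'   the species' maximum recorded lifespan, in (0, 1]. Relative age puts
#'   species with very different lifespans (cattle, 38 y; humans, 122.5 y)
#'   on a common scale, which is what makes a dual-species clock meaningful.
#' * `"loglinear"`: `log(age + offset)` below a maturity knot, continued
#'   linearly above it with matched value and slope, so the map is continuous
#'   and differentiable at the knot. This compresses juvenile ages, where
#'   methylation change per year is fastest.
#'
#' @param kind one of `"identity"`, `"relative"`, `"loglinear"`.
#' @param offset years added to age before taking the log (`"loglinear"`
#'   only). Must be positive.
#' @param maturity the knot, in years, where the loglinear transform switches
#'   from logarithmic to linear (`"loglinear"` only).
#' @return an object of class `age_transform`.
#' @examples
#' tr <- age_transform("relative")
#' transform_age(tr, 19, max_lifespan = 38) # 0.5
#' @export
age_transform <- function(kind = c("identity", "relative", "loglinear"),
                          offset = 1, maturity = 5) {
  kind <- match.arg(kind)
  if (kind == "loglinear") {
    stopifnot(is.numeric(offset), length(offset) == 1L, offset > 0,
              is.numeric(maturity), length(maturity) == 1L, maturity > 0)
  }
  structure(
    list(kind = kind,
         offset = if (kind == "loglinear") offset else NULL,
         maturity = if (kind == "loglinear") maturity else NULL),
    class = "age_transform"
  )
}

#' @export
print.age_transform <- function(x, ...) {
  cat("Age transform:", x$kind, "\n")
  if (x$kind == "loglinear")
    cat("  offset:", x$offset, "y; maturity knot:", x$maturity, "y\n")
  invisible(x)
}

#' Apply an age transform
#'
#' Maps chronological ages (years) to the regression response scale.
#' Vectorized and strictly increasing on its valid domain.
#'
#' @param transform an [age_transform()].
#' @param age_years numeric vector of positive ages in years.
#' @param max_lifespan species maximum lifespan(s) in years; required for the
#'   `"relative"` kind, either a scalar or a vector matching `age_years`.
#' @return numeric vector on the transformed scale.
#' @export
transform_age <- function(transform, age_years, max_lifespan = NULL) {
  stopifnot(inherits(transform, "age_transform"))
  switch(transform$kind,
    identity = age_years,
    relative = relative_age(age_years, max_lifespan),
    loglinear = {
      if (any(age_years + transform$offset <= 0))
        stop("loglinear transform undefined: age + offset must be positive")
      m <- transform$maturity; off <- transform$offset
      ifelse(age_years <= m,
             log(age_years + off),
             log(m + off) + (age_years - m) / (m + off))
    }
  )
}

#' Invert an age transform
#'
#' Maps values on the regression response scale back to years, such that
#' `untransform_age(tr, transform_age(tr, a, M), M) == a` to numerical
#' precision.
#'
#' @inheritParams transform_age
#' @param y numeric vector on the transformed scale.
#' @return ages in years.
#' @export
untransform_age <- function(transform, y, max_lifespan = NULL) {
  stopifnot(inherits(transform, "age_transform"))
  switch(transform$kind,
    identity = y,
    relative = {
      .check_lifespan(max_lifespan, length(y))
      y * max_lifespan
    },
    loglinear = {
      m <- transform$maturity; off <- transform$offset
      knot <- log(m + off)
      ifelse(y <= knot, exp(y) - off, m + (y - knot) * (m + off))
    }
  )
}

#' Relative age
#'
#' The ratio of chronological age to the species' maximum lifespan, a value
#' in (0, 1]. Relative age is the response of the dual-species clock: a
#' 19-year-old cow (lifespan 38 y) and a 61-year-old human (lifespan 122.5 y)
#' are both at relative age ~0.5.
#'
#' @param age_years positive ages in years.
#' @param max_lifespan positive species maximum lifespan(s) in years, scalar
#'   or matching `age_years`.
#' @return numeric vector in (0, 1].
#' @examples
#' relative_age(19, 38)       # 0.5
#' relative_age(122.5, 122.5) # 1
#' @export
relative_age <- function(age_years, max_lifespan) {
  .check_lifespan(max_lifespan, length(age_years))
  if (any(age_years <= 0))
    stop("age_years must be positive")
  bad <- which(age_years > max_lifespan)
  if (length(bad)) {
    who <- if (!is.null(names(age_years))) names(age_years)[bad] else bad
    stop("age exceeds maximum lifespan for sample(s): ",
         paste(utils::head(who, 5L), collapse = ", "))
  }
  unname(age_years / max_lifespan)
}

.check_lifespan <- function(max_lifespan, n) {
  if (is.null(max_lifespan))
    stop("max_lifespan is required for the relative age transform")
  if (!is.numeric(max_lifespan) || any(max_lifespan <= 0))
    stop("max_lifespan must be positive")
  if (!length(max_lifespan) %in% c(1L, n))
    stop("max_lifespan must be scalar or match the number of ages")
  invisible(TRUE)
}
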