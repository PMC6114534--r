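#' Budding grading schemes
#'
#' Two published stratifications of the absolute bud count per core/field:
#'
#' * `satoh`: five grades — grade 0 with 0 buds, grade 1 with 1-5, grade 2
#'   with 6-10, grade 3 with 10-19, grade 4 with >= 20.
#' * `harbaum`: four grades with the printed intervals `[0-5]`, `[5-17]`,
#'   `[17-20]`, `[20-Inf]` for grades 1-4.
#'
#' Both published interval lists share endpoints (Satoh prints 10 in two
#' intervals; Harbaum prints 5, 17 and 20 in two). The `boundary` switch
#' resolves a count equal to a shared endpoint: `"lower"` (default,
#' conservative) assigns it to the lower grade, `"upper"` to the higher.
#'
#' @param name `"satoh"` or `"harbaum"`, or a path to a YAML file with
#'   fields `name`, `grades` and `lower_bounds` to supply a custom scheme.
#' @param boundary `"lower"` or `"upper"` shared-endpoint resolution.
#' @return an object of class `gradingScheme`: list with `name`, `grades`,
#'   `printed_lower` (printed interval lower bounds) and `cutoffs` (the
#'   effective first count of each grade after boundary resolution).
#' @export
gradingScheme <- function(name = c("satoh", "harbaum"),
                          boundary = c("lower", "upper")) {
  boundary <- match.arg(boundary)
  if (file.exists(name[1])) {
    y <- yaml::read_yaml(name[1])
    schemes <- list(list(name = y$name, grades = as.integer(y$grades),
                         lower = as.numeric(y$lower_bounds),
                         shared = as.numeric(y$shared_endpoints %||% numeric())))
    names(schemes) <- y$name
    name <- y$name
  } else {
    name <- match.arg(name)
    schemes <- list(
      ## printed: {0}, 1-5, 6-10, 10-19, >=20 (10 appears twice)
      satoh = list(name = "satoh", grades = 0:4,
                   lower = c(0, 1, 6, 10, 20), shared = 10),
      ## printed: [0-5], [5-17], [17-20], [20-Inf]
      harbaum = list(name = "harbaum", grades = 1:4,
                     lower = c(0, 5, 17, 20), shared = c(5, 17, 20)))
  }
  s <- schemes[[name]]
  cut <- s$lower
  if (boundary == "lower") {
    ## a count equal to a shared endpoint belongs to the lower grade, so the
    ## higher grade effectively starts one count later
    cut[cut %in% s$shared] <- cut[cut %in% s$shared] + 1
  }
  structure(list(name = s$name, grades = s$grades, printed_lower = s$lower,
                 shared = s$shared, cutoffs = cut, boundary = boundary),
            class = "gradingScheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grade a bud count
#'
#' Maps a non-negative integer bud count to its budding grade under the
#' chosen scheme. Every count maps to exactly one grade and the mapping is
#' non-decreasing in the count.
#'
#' @param count non-negative bud count (vectorized).
#' @param scheme a [gradingScheme()].
#' @return integer grade(s).
#' @export
budGrade <- function(count, scheme = gradingScheme("satoh")) {
  if (any(count < 0)) stop("bud counts must be non-negative")
  idx <- findInterval(count, scheme$cutoffs)
  if (any(idx < 1)) stop("count below the first grade interval")
  as.integer(scheme$grades[idx])
}

#' Write a grading scheme to YAML
#'
#' @param scheme a [gradingScheme()].
#' @param path output file.
#' @export
writeGradingScheme <- function(scheme, path) {
  yaml::write_yaml(list(name = scheme$name,
                        grades = scheme$grades,
                        lower_bounds = scheme$printed_lower,
                        shared_endpoints = scheme$shared,
                        boundary = scheme$boundary), path)
  invisible(path)
}

#' @export
print.gradingScheme <- function(x, ...) {
  cat(sprintf("Grading scheme '%s' (%s-boundary):\n", x$name, x$boundary))
  up <- c(x$cutoffs[-1] - 1, Inf)
  for (i in seq_along(x$grades))
    cat(sprintf("  grade %d: %g-%g buds\n", x$grades[i], x$cutoffs[i], up[i]))
  invisible(x)
}
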