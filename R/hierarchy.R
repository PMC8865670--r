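#' Directed influence asymmetry index
#'
#' For a nonnegative between-area connection matrix `e` with element
#' `e[i, j]` holding the loading of the connection from area j to area i
#' (source = column), computes `DAI[i, j] = (e[i, j] - e[j, i]) /
#' (e[i, j] + e[j, i])`. Pairs with no connectivity in either direction get
#' 0; the diagonal is 0. The result is antisymmetric with values in
#' the interval -1..1; positive `DAI[i, j]` means j drives i more than the reverse.
#'
#' @param e nonnegative area x area matrix (diagonal ignored). A named
#'   connection-loading vector over ordered area pairs (labels
#'   `"src->tgt"`) is also accepted.
#' @param areas area labels (required if `e` is a vector without labels).
#'
#' @return The DAI matrix (area x area, antisymmetric, zero diagonal).
#' @export
dai_matrix <- function(e, areas = NULL) {
  if (is.vector(e)) e <- connection_vector_to_matrix(e, areas)
  if (any(e < 0)) stopf("connection loadings must be nonnegative")
  diag(e) <- 0
  num <- e - t(e)
  den <- e + t(e)
  dai <- ifelse(den > 0, num / den, 0)
  diag(dai) <- 0
  dimnames(dai) <- dimnames(e)
  dai
}

# named connection vector ("src->tgt") -> matrix with e[i,j] = j -> i
connection_vector_to_matrix <- function(e, areas = NULL) {
  labs <- names(e)
  if (is.null(labs)) stopf("connection vector must carry 'src->tgt' names")
  parts <- strsplit(labs, "->", fixed = TRUE)
  src <- vapply(parts, `[`, "", 1)
  tgt <- vapply(parts, `[`, "", 2)
  areas <- areas %||% intersect(c(default_areas(), unique(c(src, tgt))),
                                unique(c(src, tgt)))
  m <- matrix(0, length(areas), length(areas),
              dimnames = list(target = areas, source = areas))
  m[cbind(match(tgt, areas), match(src, areas))] <- as.numeric(e)
  m
}

#' Functional hierarchy scores from a DAI matrix
#'
#' Scales the DAI matrix onto the interval -2.5..2.5 (a fixed factor of 2.5, mapping
#' the attainable -1..1 range onto six hierarchy levels; `scaling =
#' "minmax"` rescales the observed extremes instead), then, per target
#' area, shifts the DAIs from all source areas so that the smallest value
#' is 1, and aggregates the shifted row into a per-area score `H` (mean
#' over sources by default; `aggregate = "sum"` reproduces the summed
#' variant — the ranking is identical for complete matrices). Lower `H`
#' means the area drives the others more strongly (bottom of the
#' functional hierarchy).
#'
#' @param dai antisymmetric DAI matrix (from [dai_matrix()]).
#' @param scaling `"fixed"` (factor 2.5) or `"minmax"`.
#' @param aggregate `"mean"` or `"sum"`.
#'
#' @return A `hierarchy_result`: list with `dai`, `scaled`, `shifted`, and
#'   `scores` (tibble: `area`, `H`, `rank`).
#' @export
hierarchy_scores <- function(dai, scaling = c("fixed", "minmax"),
                             aggregate = c("mean", "sum")) {
  scaling <- match.arg(scaling)
  aggregate <- match.arg(aggregate)
  if (max(abs(dai + t(dai))) > 1e-8) stopf("DAI matrix is not antisymmetric")
  n <- nrow(dai)
  scaled <- if (scaling == "fixed") {
    2.5 * dai
  } else {
    mx <- max(abs(dai[row(dai) != col(dai)]))
    if (mx > 0) 2.5 * dai / mx else dai
  }
  shifted <- scaled
  for (i in seq_len(n)) { # row i: target area, entries from all sources
    off <- setdiff(seq_len(n), i)
    shifted[i, off] <- scaled[i, off] + (1 - min(scaled[i, off]))
    shifted[i, i] <- NA_real_
  }
  H <- vapply(seq_len(n), function(i) {
    v <- shifted[i, setdiff(seq_len(n), i)]
    if (aggregate == "mean") mean(v) else sum(v)
  }, 0)
  areas <- rownames(dai) %||% paste0("area", seq_len(n))
  structure(
    list(dai = dai, scaled = scaled, shifted = shifted,
         scores = tibble::tibble(area = areas, H = H, rank = rank(H))),
    class = "hierarchy_result"
  )
}

#' @export
print.hierarchy_result <- function(x, ...) {
  cat("<hierarchy_result>\n")
  ord <- order(x$scores$H)
  cat(sprintf("  hierarchy (bottom first): %s\n",
              paste(x$scores$area[ord], collapse = " < ")))
  invisible(x)
}

#' @export
tidy.hierarchy_result <- function(x, ...) x$scores

#' Hierarchy from a component's connection loadings
#'
#' Convenience wrapper: builds the target x source connection matrix from a
#' `parafac_model` component's connection loading, computes the DAI matrix
#' and the hierarchy scores.
#'
#' @param model a `parafac_model` whose connection axis carries
#'   `"src->tgt"` labels.
#' @param k component index.
#' @inheritParams hierarchy_scores
#' @return A `hierarchy_result`.
#' @export
component_hierarchy <- function(model, k, scaling = "fixed",
                                aggregate = "mean") {
  e <- setNames(model$loadings$connection[, k],
                as.character(model$axes$connection))
  hierarchy_scores(dai_matrix(e), scaling = scaling, aggregate = aggregate)
}

#' @export
autoplot.hierarchy_result <- function(object, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$area, .data$H),
                                   y = .data$H)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "area (bottom of hierarchy first)",
                  y = "hierarchy score H") +
    ggplot2::theme_minimal()
}
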