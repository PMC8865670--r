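#' Current source density from a laminar LFP depth profile
#'
#' Estimates CSD as the negative second spatial difference of the
#' trial-averaged LFP across depth, `-(x[d-1,] - 2 x[d,] + x[d+1,]) / h^2`,
#' so that current sinks are negative. The two edge channels are dropped
#' (no padding).
#'
#' @param profile numeric matrix, depth x time: trial-averaged LFP, ordered
#'   from superficial to deep.
#' @param spacing inter-channel spacing in micrometers.
#' @param depths optional channel depths (micrometers), length `nrow(profile)`.
#'
#' @return A `csd_profile`: list with `values` ((depth-2) x time matrix),
#'   `depths` (interior channel depths), and `spacing`.
#' @export
compute_csd <- function(profile, spacing, depths = NULL) {
  if (!is.matrix(profile)) profile <- as.matrix(profile)
  nd <- nrow(profile)
  if (nd < 3) stopf("CSD needs at least 3 depth channels, got %d", nd)
  if (is.null(depths)) depths <- (seq_len(nd) - 1) * spacing
  i <- 2:(nd - 1)
  vals <- -(profile[i - 1, , drop = FALSE] - 2 * profile[i, , drop = FALSE] +
              profile[i + 1, , drop = FALSE]) / spacing^2
  structure(list(values = vals, depths = depths[i], spacing = spacing),
            class = "csd_profile")
}

#' @export
print.csd_profile <- function(x, ...) {
  cat(sprintf("<csd_profile> %d depths x %d samples, spacing %g um\n",
              nrow(x$values), ncol(x$values), x$spacing))
  invisible(x)
}

#' Depth priors for layer-representative channels
#'
#' Mean and standard deviation (micrometers) of the cortical depth of the
#' channels representing each layer in each visual area, used to constrain
#' automated layer assignment.
#'
#' @return A tibble with columns `area`, `layer`, `mean`, `sd`.
#' @export
layer_depth_priors <- function() {
  areas <- default_areas()
  means <- rbind(
    L1 = c(80, 87, 76, 73, 80, 80),
    L2 = c(160, 167, 156, 149, 183, 164),
    L3 = c(255, 253, 244, 233, 297, 269),
    L4 = c(407, 400, 360, 356, 451, 407),
    L5 = c(542, 560, 511, 495, 583, 545),
    L6 = c(785, 767, 733, 720, 777, 764)
  )
  sds <- rbind(
    L1 = c(25, 39, 13, 24, 0, 25),
    L2 = c(25, 39, 13, 31, 31, 28),
    L3 = c(32, 41, 13, 35, 31, 40),
    L4 = c(39, 51, 35, 52, 30, 50),
    L5 = c(55, 51, 52, 60, 31, 48),
    L6 = c(70, 39, 45, 82, 39, 55)
  )
  colnames(means) <- colnames(sds) <- areas
  out <- expand.grid(layer = rownames(means), area = areas,
                     stringsAsFactors = FALSE)
  out$mean <- mapply(function(l, a) means[l, a], out$layer, out$area)
  out$sd <- mapply(function(l, a) sds[l, a], out$layer, out$area)
  tibble::as_tibble(out[, c("area", "layer", "mean", "sd")])
}

#' Assign layer-representative channels from a CSD profile
#'
#' For each layer, selects the channel whose depth lies within the prior
#' mean +/- 2 SD and whose CSD profile carries the most source/sink energy
#' (root-mean-square over time); ties are broken by proximity to the prior
#' mean, so the choice is deterministic. SD-zero priors are widened to a
#' half channel spacing.
#'
#' @param csd a `csd_profile` from [compute_csd()].
#' @param priors tibble with columns `layer`, `mean`, `sd` (micrometers),
#'   e.g. one area's rows of [layer_depth_priors()].
#' @param override optional tibble with columns `layer`, `channel` taking
#'   precedence over the automated pick (manual layer table).
#'
#' @return A tibble with columns `layer`, `channel` (index into the CSD
#'   depths), `depth`.
#' @export
assign_layers <- function(csd, priors, override = NULL) {
  priors <- tibble::as_tibble(priors)
  energy <- sqrt(rowMeans(csd$values^2))
  picks <- purrr::pmap_dfr(priors, function(layer, mean, sd, ...) {
    tol <- max(2 * sd, csd$spacing / 2)
    ok <- which(abs(csd$depths - mean) <= tol)
    if (!length(ok)) stopf("no channel within 2 SD of the %s depth prior (%g +/- %g um)", layer, mean, sd)
    best <- ok[order(-energy[ok], abs(csd$depths[ok] - mean))][1]
    tibble::tibble(layer = layer, channel = best, depth = csd$depths[best])
  })
  if (!is.null(override) && nrow(override)) {
    override <- tibble::as_tibble(override)
    for (i in seq_len(nrow(override))) {
      j <- which(picks$layer == override$layer[i])
      picks$channel[j] <- override$channel[i]
      picks$depth[j] <- csd$depths[override$channel[i]]
    }
  }
  picks
}
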