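#' Synthetic geodesic-style EEG montage
#'
#' Places `n` electrodes quasi-uniformly over the upper hemisphere of a
#' sphere (golden-angle spiral), mimicking the coverage of a geodesic
#' sensor net. Coordinates follow the usual EEG convention: +x right,
#' +y anterior, +z up, origin at the head centre. The vertex reference
#' site is excluded, matching recordings where the reference electrode
#' is not reinstated.
#'
#' @param n number of recording channels
#' @param radius head radius in metres
#' @param max_polar_deg lowest electrode row, degrees of polar angle
#'   from the vertex (90 = equator, >90 dips below it)
#' @return data.frame with columns `label`, `x_m`, `y_m`, `z_m`
#' @export
make_montage <- function(n = 32, radius = 0.09, max_polar_deg = 100) {
  if (n < 2) stop_atersp("config", "montage needs >= 2 channels")
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  # polar angle grows as sqrt for ~uniform area; skip the vertex itself
  theta <- (max_polar_deg * pi / 180) * sqrt((i - 0.25) / n)
  phi <- i * golden
  data.frame(
    label = sprintf("E%03d", i),
    x_m = radius * sin(theta) * cos(phi),
    y_m = radius * sin(theta) * sin(phi),
    z_m = radius * cos(theta)
  )
}

# Canonical scalp-region direction vectors (unit, EEG convention).
REGION_DIRECTIONS <- list(
  sensorimotor_left  = c(-0.71, 0.00, 0.71),
  sensorimotor_right = c( 0.71, 0.00, 0.71),
  parietal_left      = c(-0.50, -0.55, 0.67),
  parietal_right     = c( 0.50, -0.55, 0.67),
  frontal_left       = c(-0.45, 0.60, 0.66),
  frontal_right      = c( 0.45, 0.60, 0.66),
  occipital          = c( 0.00, -0.85, 0.53)
)

#' Channel groups by scalp region
#'
#' Assigns, for each named scalp region, the `k` montage channels whose
#' positions are angularly closest to the region's canonical direction.
#' These groups are the targets for injected effects and the regions
#' reported by cluster overlap checks.
#'
#' @param montage montage data.frame from [make_montage()]
#' @param k channels per group
#' @param regions subset of region names; default all
#' @return named list of character vectors of channel labels
#' @export
channel_groups <- function(montage, k = 5,
                           regions = names(REGION_DIRECTIONS)) {
  bad <- setdiff(regions, names(REGION_DIRECTIONS))
  if (length(bad))
    stop_atersp("config", "unknown region(s): %s",
                paste(bad, collapse = ", "))
  pos <- as.matrix(montage[, c("x_m", "y_m", "z_m")])
  pos <- pos / sqrt(rowSums(pos^2))
  out <- lapply(regions, function(r) {
    d <- pos %*% REGION_DIRECTIONS[[r]]
    montage$label[order(-d)[seq_len(min(k, nrow(montage)))]]
  })
  names(out) <- regions
  out
}

#' Read / write a montage TSV (label, x_m, y_m, z_m)
#' @param path file path
#' @return data.frame (for the reader)
#' @export
read_montage_tsv <- function(path) {
  m <- read_tsv(path)
  need <- c("label", "x_m", "y_m", "z_m")
  if (!all(need %in% names(m)))
    stop_atersp("io", "montage file '%s' lacks columns %s", path,
                paste(setdiff(need, names(m)), collapse = ", "))
  m
}

#' @rdname read_montage_tsv
#' @param montage montage data.frame
#' @export
write_montage_tsv <- function(montage, path) write_tsv(montage, path)
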