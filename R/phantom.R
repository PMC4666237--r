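#' Synthetic brain-slice phantom specification
#'
#' Describes a 256 x 256 axial-slice phantom: dark background, an
#' elliptical "brain" with a white-matter rim and a gray-matter interior,
#' and three bilateral pairs of small elliptical deep-gray structures
#' (caudate / putamen / thalamus analogues) placed inside the central
#' 100 x 100 window that [extract_roi()] selects, plus additive Gaussian
#' noise. Intensities are chosen far from 0/255 so that noise clipping
#' bias is negligible.
#'
#' @param size image `(rows, cols)`; default `c(256, 256)`.
#' @param background_level background intensity (default 10).
#' @param tissue_levels `(wm, gm)` intensities (default `c(170, 110)`).
#' @param structure_specs data frame with columns `name`, `center_row`,
#'   `center_col`, `semi_row`, `semi_col`, `intensity`; defaults are three
#'   bilateral pairs at intensities 60, 80 and 140.
#' @param noise_sd standard deviation of the additive Gaussian noise in
#'   intensity units (default 5).
#' @param seed RNG seed for the noise (default 1).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256L, 256L), background_level = 10L,
                         tissue_levels = c(wm = 170L, gm = 110L),
                         structure_specs = default_structures(size),
                         noise_sd = 5, seed = 1L) {
  if (any(c(background_level, tissue_levels,
            structure_specs$intensity) < 0) ||
      any(c(background_level, tissue_levels,
            structure_specs$intensity) > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  structure(list(size = as.integer(size),
                 background_level = as.integer(background_level),
                 tissue_levels = stats::setNames(as.integer(tissue_levels),
                                                names(tissue_levels)),
                 structure_specs = structure_specs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# bilateral caudate / putamen / thalamus analogues; at the default 256x256
# size all six lie inside the central 100x100 window (rows/cols 79..178,
# 1-based). Geometry scales with the image size.
default_structures <- function(size = c(256L, 256L)) {
  fr <- size[1L] / 256; fc <- size[2L] / 256
  data.frame(
    name = c("caudate_l", "caudate_r", "putamen_l", "putamen_r",
             "thalamus_l", "thalamus_r"),
    center_row = c(106, 106, 130, 130, 152, 152) * fr,
    center_col = c(112, 144, 103, 153, 114, 142) * fc,
    semi_row = c(12, 12, 14, 14, 12, 12) * fr,
    semi_col = c(8, 8, 9, 9, 10, 10) * fc,
    intensity = c(60L, 60L, 80L, 80L, 140L, 140L),
    stringsAsFactors = FALSE
  )
}

ellipse_mask <- function(m, n, cr, cc, sr, sc) {
  r <- matrix(seq_len(m), m, n)
  c_ <- matrix(seq_len(n), m, n, byrow = TRUE)
  ((r - cr) / sr)^2 + ((c_ - cc) / sc)^2 <= 1
}

#' Generate a synthetic brain phantom with ground-truth labels
#'
#' Renders the phantom described by a [phantom_spec()], adds Gaussian noise
#' truncated by clipping to `[0, 255]`, and returns both the 8-bit image
#' and an integer label mask: 0 background, 1 white-matter rim, 2
#' gray-matter interior, `2 + k` the k-th structure of
#' `spec$structure_specs`. The same spec (including its seed) yields
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [gray_image()]), `labels` (integer matrix)
#'   and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  m <- spec$size[1L]; n <- spec$size[2L]
  cr <- (m + 1) / 2; cc <- (n + 1) / 2
  brain_sr <- 0.40 * m; brain_sc <- 0.345 * n
  gm_sr <- 0.275 * m; gm_sc <- 0.215 * n
  brain <- ellipse_mask(m, n, cr, cc, brain_sr, brain_sc)
  gm <- ellipse_mask(m, n, cr, cc, gm_sr, gm_sc)
  labels <- matrix(0L, m, n)
  labels[brain] <- 1L
  labels[gm] <- 2L
  base <- matrix(as.numeric(spec$background_level), m, n)
  base[brain] <- spec$tissue_levels[[1L]]
  base[gm] <- spec$tissue_levels[[2L]]
  ss <- spec$structure_specs
  for (k in seq_len(nrow(ss))) {
    sm <- ellipse_mask(m, n, ss$center_row[k], ss$center_col[k],
                       ss$semi_row[k], ss$semi_col[k])
    if (any(sm & !brain))
      stop(sprintf("structure '%s' extends outside the brain ellipse",
                   ss$name[k]), call. = FALSE)
    base[sm] <- ss$intensity[k]
    labels[sm] <- 2L + k
  }
  noisy <- if (spec$noise_sd > 0) {
    with_local_seed(spec$seed,
                    base + rnorm(m * n, mean = 0, sd = spec$noise_sd))
  } else base
  px <- matrix(as.integer(clip(round_half_away(noisy), 0, 255)), m, n)
  list(image = gray_image(px, 255L), labels = labels, spec = spec)
}

#' Mean-intensity contrast between structures and surrounding tissue
#'
#' For each structure label, the absolute difference between the mean
#' intensity over the structure's pixels and the mean intensity over the
#' gray-matter pixels, optionally restricted to a window (use the ROI
#' window so the comparison involves only pixels the enhancement can
#' touch).
#'
#' @param img a [gray_image()].
#' @param labels label matrix from [generate_phantom()].
#' @param window optional [roi_window()]; when given, only pixels inside it
#'   are used.
#' @return named numeric vector of contrasts, one per structure label
#'   present.
#' @export
structure_contrast <- function(img, labels, window = NULL) {
  img <- as_gray_image(img)
  px <- img$pixels
  if (!is.null(window)) {
    rows <- window$origin[1L] + seq_len(nrow(window$pixels)) - 1L
    cols <- window$origin[2L] + seq_len(ncol(window$pixels)) - 1L
    px <- px[rows, cols, drop = FALSE]
    labels <- labels[rows, cols, drop = FALSE]
  }
  tissue_mean <- mean(px[labels == 2L])
  labs <- sort(unique(labels[labels >= 3L]))
  out <- vapply(labs, function(l) abs(mean(px[labels == l]) - tissue_mean),
                numeric(1))
  names(out) <- as.character(labs)
  out
}

#' Read a phantom specification from a key-value file
#'
#' Plain-text `key = value` lines; unknown keys are an error. Supported
#' keys: `rows`, `cols`, `background_level`, `wm`, `gm`, `noise_sd`,
#' `seed`. Structure geometry always uses the package defaults.
#'
#' @param path file path.
#' @return a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  kv <- read_key_values(path)
  allowed <- c("rows", "cols", "background_level", "wm", "gm", "noise_sd",
               "seed")
  bad <- setdiff(names(kv), allowed)
  if (length(bad))
    stop("unknown phantom spec keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  num <- function(key, default) if (key %in% names(kv))
    as.numeric(kv[[key]]) else default
  phantom_spec(size = c(num("rows", 256), num("cols", 256)),
               background_level = num("background_level", 10),
               tissue_levels = c(wm = num("wm", 170), gm = num("gm", 110)),
               noise_sd = num("noise_sd", 5),
               seed = num("seed", 1))
}

# `key = value` file parser shared by phantom and CLI configs
read_key_values <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    kv[[trimws(parts[1L])]] <- trimws(parts[2L])
  }
  kv
}
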