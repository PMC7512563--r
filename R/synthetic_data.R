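# Brain-like phantom generator. Stands in for slice datasets of real MRI
# scans: a concentric-ellipse head with CSF/GM/WM bands, an optional
# hyperintense focal lesion defining the malignant class, and Rician
# magnitude noise at a requested SNR. Dataset generation emulates
# T2-weighted contrast (bright CSF, dark WM), the modality on which focal
# lesions are hyperintense against their white-matter surround.

#' Phantom specification
#'
#' @param size image side length in pixels (default 128).
#' @param tissue_intensities named numeric vector with entries
#'   \code{background, csf, gm, wm} in \[0, 1\]; the default
#'   0.0 / 0.3 / 0.6 / 0.9 is a T1-like contrast. Dataset presets use the
#'   T2-weighted map \code{c(0, 0.9, 0.6, 0.35)} instead (see
#'   \code{make_dataset}).
#' @param band_fractions named vector \code{c(csf = , gm = )}: fractions of
#'   the normalized elliptical radius where the CSF band and the GM band
#'   begin (WM core inside, defaults 0.88 / 0.70, jittered per draw).
#' @param lesion_present does the phantom carry a lesion (malignant class)?
#' @param n_lesions number of lesion discs (default 2).
#' @param lesion_radius_range pixel radius interval for each disc
#'   (default c(6, 11) on a 128 grid; discs must fit inside the WM core).
#' @param lesion_intensity disc intensity, hyperintense against white
#'   matter (default 1.0).
#' @param snr_db Rician noise level in dB, or \code{NULL} for a clean image.
#' @param seed integer seed for this phantom's randomness.
#' @return a \code{phantom_spec} list.
#' @export
phantom_spec <- function(size = 128L,
                         tissue_intensities = c(background = 0, csf = 0.3,
                                                gm = 0.6, wm = 0.9),
                         band_fractions = c(csf = 0.88, gm = 0.70),
                         lesion_present = FALSE,
                         n_lesions = 2L,
                         lesion_radius_range = c(6, 11),
                         lesion_intensity = 1.0,
                         snr_db = NULL,
                         seed = 1L) {
  stopifnot(size >= 16L,
            all(tissue_intensities >= 0), all(tissue_intensities <= 1),
            all(c("background", "csf", "gm", "wm") %in% names(tissue_intensities)),
            all(c("csf", "gm") %in% names(band_fractions)),
            band_fractions[["gm"]] < band_fractions[["csf"]],
            lesion_radius_range[1] <= lesion_radius_range[2],
            lesion_intensity >= 0, lesion_intensity <= 1)
  structure(list(size = as.integer(size),
                 tissue_intensities = tissue_intensities,
                 band_fractions = band_fractions,
                 lesion_present = isTRUE(lesion_present),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_range = lesion_radius_range,
                 lesion_intensity = lesion_intensity,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom image
#'
#' Concentric-ellipse head: background outside the skull ellipse, an outer
#' CSF band, a GM band and a WM core. Each draw jitters the ellipse
#' semi-axes (about +/-1%), the band fractions (+/-0.005) and the
#' orientation (about +/-10 degrees; axial slices are approximately
#' orientation-normalized in practice). If the spec asks for lesions,
#' discs of random radius and position are placed fully inside the WM core
#' (bounded retries) at the lesion intensity.
#'
#' @param spec a \code{phantom_spec}.
#' @param rng an \code{rng_stream}; defaults to one seeded from
#'   \code{spec$seed}.
#' @return numeric matrix in \[0, 1\] (clean; apply \code{add_rician_noise()}
#'   or use \code{make_dataset()} for noisy images).
#' @export
make_phantom <- function(spec, rng = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(rng)) rng <- rng_stream(spec$seed)
  n <- spec$size
  ti <- spec$tissue_intensities
  cx <- (n + 1) / 2
  a <- with_rng(rng, stats::runif(1, 0.415, 0.425)) * n   # semi-axes
  b <- with_rng(rng, stats::runif(1, 0.325, 0.335)) * n
  th <- with_rng(rng, stats::runif(1, -0.17, 0.17))
  xy <- expand.grid(row = seq_len(n), col = seq_len(n))
  dx <- xy$col - cx; dy <- xy$row - cx
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  r <- sqrt((u / a)^2 + (v / b)^2)  # normalized elliptical radius
  t_csf <- spec$band_fractions[["csf"]] +
    with_rng(rng, stats::runif(1, -0.005, 0.005))
  t_gm <- spec$band_fractions[["gm"]] +
    with_rng(rng, stats::runif(1, -0.005, 0.005))
  val <- ifelse(r > 1, ti[["background"]],
                ifelse(r > t_csf, ti[["csf"]],
                       ifelse(r > t_gm, ti[["gm"]], ti[["wm"]])))
  img <- matrix(val, n, n)

  if (spec$lesion_present) {
    rr <- matrix(r, n, n)
    for (k in seq_len(spec$n_lesions)) {
      placed <- FALSE
      for (try in 1:200) {
        rad <- with_rng(rng, stats::runif(1, spec$lesion_radius_range[1],
                                          spec$lesion_radius_range[2]))
        px <- with_rng(rng, stats::runif(1, rad + 1, n - rad - 1))
        py <- with_rng(rng, stats::runif(1, rad + 1, n - rad - 1))
        d2 <- outer((seq_len(n) - py)^2, rep(1, n)) +
          t(outer((seq_len(n) - px)^2, rep(1, n)))
        disc <- d2 <= rad^2
        # disc must sit fully inside the WM core
        if (all(rr[disc] <= t_gm)) {
          img[disc] <- spec$lesion_intensity
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place lesion inside the white-matter core",
                        call. = FALSE)
    }
  }
  img
}

#' Add Rician noise at a target SNR
#'
#' MRI magnitude noise: each output pixel is
#' \eqn{\sqrt{(I + n_1)^2 + n_2^2}} with \eqn{n_1, n_2} independent
#' zero-mean Gaussians of standard deviation
#' \eqn{\sigma_n = \mathrm{rms}(I) / 10^{\mathrm{SNR_{dB}}/20}}.
#' \code{snr_db >= 200} is treated as the noiseless limit. The magnitude is
#' unbounded above; consumers that need \[0, 1\] rescale downstream.
#'
#' @param img numeric matrix with non-negative entries, not all zero.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param rng an \code{rng_stream}.
#' @return noisy magnitude image (entries >= 0).
#' @export
add_rician_noise <- function(img, snr_db, rng) {
  stopifnot(is.matrix(img), is.finite(snr_db))
  rms <- sqrt(mean(img^2))
  if (rms == 0) stop("cannot set an SNR for an all-zero image", call. = FALSE)
  if (snr_db >= 200) return(abs(img))
  sigma_n <- rms / 10^(snr_db / 20)
  n1 <- with_rng(rng, stats::rnorm(length(img), 0, sigma_n))
  n2 <- with_rng(rng, stats::rnorm(length(img), 0, sigma_n))
  matrix(sqrt((as.numeric(img) + n1)^2 + n2^2), nrow(img), ncol(img))
}

# T2-weighted tissue contrast used for dataset emulation: bright CSF,
# mid GM, dark WM, so focal lesions at ~1.0 are strongly hyperintense
# against their white-matter surround.
.t2_intensities <- c(background = 0, csf = 0.9, gm = 0.6, wm = 0.35)

# deterministic per-subtype lesion profile for the 17 malignant subtypes:
# lesion count, radius range and contrast vary across subtypes
.subtype_profile <- function(subtype) {
  s <- as.integer(subtype)
  list(
    n_lesions = 1L + (s - 1L) %% 2L,
    radius_range = c(5 + s %% 3, 9 + s %% 3),
    intensity = c(0.95, 1.0)[1L + s %% 2L]
  )
}

#' Generate a labeled phantom dataset
#'
#' Benign phantoms carry no lesion; malignant phantoms carry hyperintense
#' white-matter lesions. All dataset images use T2-weighted tissue contrast
#' (\code{c(0, 0.9, 0.6, 0.35)}). Two presets emulate the two experimental
#' regimes:
#' \describe{
#'   \item{\code{"aanlib"}}{a 90-slice collection: 18 subtypes x 5
#'     replicates — 1 benign subtype and 17 malignant subtypes differing in
#'     lesion count, size and contrast (5 benign + 85 malignant images).}
#'   \item{\code{"sbd"}}{the noise-sweep regime: 45 benign + 45 malignant
#'     replicates of the same anatomy with the default lesion profile,
#'     intended to be generated at each SNR level.}
#' }
#' Without a preset, \code{n_benign} + \code{n_malignant} images are drawn
#' with the default lesion profile.
#'
#' @param n_benign,n_malignant image counts (ignored under a preset).
#' @param snr_db Rician noise level in dB (use \code{Inf} or >= 200 for
#'   clean images).
#' @param seed master seed for the data stream.
#' @param size image side length (default 128).
#' @param preset \code{NULL}, \code{"aanlib"} or \code{"sbd"}.
#' @param tissue_intensities tissue contrast map (default T2-weighted).
#' @return tibble with columns \code{id}, \code{image} (list of matrices),
#'   \code{label} (+1 malignant / -1 benign), \code{class}, \code{subtype},
#'   \code{snr_db}, \code{seed}.
#' @export
make_dataset <- function(n_benign, n_malignant, snr_db, seed,
                         size = 128L, preset = NULL,
                         tissue_intensities = .t2_intensities) {
  rng <- rng_substream(seed, 0L)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("aanlib", "sbd"))
    plan <- if (preset == "aanlib") {
      expand.grid(rep = 1:5, subtype = 0:17)
    } else {
      data.frame(rep = c(1:45, 1:45), subtype = rep(c(0L, 1L), each = 45))
    }
  } else {
    stopifnot(n_benign >= 1L, n_malignant >= 1L)
    plan <- data.frame(
      rep = c(seq_len(n_benign), seq_len(n_malignant)),
      subtype = c(rep.int(0L, n_benign), rep.int(1L, n_malignant))
    )
  }
  aanlib <- !is.null(preset) && preset == "aanlib"
  sc <- size / 128  # lesion radii are specified on the 128 grid
  imgs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    s <- plan$subtype[i]
    if (s == 0L) {
      sp <- phantom_spec(size = size, tissue_intensities = tissue_intensities,
                         lesion_present = FALSE)
    } else if (aanlib) {
      pr <- .subtype_profile(s)
      sp <- phantom_spec(size = size, tissue_intensities = tissue_intensities,
                         lesion_present = TRUE,
                         n_lesions = pr$n_lesions,
                         lesion_radius_range = pmax(pr$radius_range * sc, 2),
                         lesion_intensity = pr$intensity)
    } else {
      sp <- phantom_spec(size = size, tissue_intensities = tissue_intensities,
                         lesion_present = TRUE,
                         lesion_radius_range = pmax(c(6, 11) * sc, 2))
    }
    img <- make_phantom(sp, rng)
    if (is.finite(snr_db) && snr_db < 200) {
      img <- add_rician_noise(img, snr_db, rng)
    }
    imgs[[i]] <- img
  }
  tibble::tibble(
    id = sprintf("img%03d", seq_len(nrow(plan))),
    image = imgs,
    label = ifelse(plan$subtype == 0L, -1, 1),
    class = ifelse(plan$subtype == 0L, "benign", "malignant"),
    subtype = as.integer(plan$subtype),
    snr_db = as.numeric(snr_db),
    seed = as.integer(seed)
  )
}

#' Write a dataset's images and manifest to disk
#'
#' Each image becomes an 8-bit grayscale PNG (intensities rescaled by the
#' image maximum when noise pushes them above 1); the manifest CSV lists
#' \code{filename, label, class, subtype, snr_db, seed}.
#'
#' @param data a tibble from \code{make_dataset()}.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fn <- paste0(data$id, ".png")
  for (i in seq_len(nrow(data))) {
    img <- data$image[[i]]
    if (max(img) > 1) img <- img / max(img)
    write_gray_image(img, file.path(dir, fn[i]))
  }
  manifest <- data.frame(filename = fn, label = data$label,
                         class = data$class, subtype = data$subtype,
                         snr_db = data$snr_db, seed = data$seed)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from a manifest CSV
#'
#' @param manifest_path path to a manifest written by
#'   \code{write_dataset()} (or any CSV with \code{filename} and
#'   \code{label} columns; paths resolved relative to the manifest).
#' @return tibble in the \code{make_dataset()} layout.
#' @export
read_dataset <- function(manifest_path) {
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("filename", "label") %in% names(m))) {
    stop("manifest must have `filename` and `label` columns", call. = FALSE)
  }
  dir <- dirname(manifest_path)
  imgs <- lapply(m$filename, function(f) read_gray_image(file.path(dir, f)))
  tibble::tibble(
    id = tools::file_path_sans_ext(m$filename),
    image = imgs,
    label = as.numeric(m$label),
    class = if ("class" %in% names(m)) m$class else
      ifelse(m$label > 0, "malignant", "benign"),
    subtype = if ("subtype" %in% names(m)) as.integer(m$subtype) else NA_integer_,
    snr_db = if ("snr_db" %in% names(m)) as.numeric(m$snr_db) else NA_real_,
    seed = if ("seed" %in% names(m)) as.integer(m$seed) else NA_integer_
  )
}
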