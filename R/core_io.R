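#' @useDynLib regsynth, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm median optim predict quantile rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Coordinate convention (used everywhere in the package):
#   images are matrices M[row, col]; row indexes y, col indexes x, both
#   0-based internally. Physical position of pixel (row r, col c) is
#   (x, y) = (c * spacing, r * spacing) mm, origin at the centre of the
#   first pixel. Landmarks and displacement fields are stored in mm.
# ---------------------------------------------------------------------------

#' 2D grayscale image with pixel spacing
#'
#' Container for a single-channel 2D image on a regular grid with known
#' isotropic pixel size. Intensities are arbitrary units; images read from
#' disk are rescaled to \[0, 255\].
#'
#' @param pixels numeric matrix of intensities (rows = y, cols = x).
#' @param spacing isotropic pixel size in mm (> 0).
#' @param mask optional logical matrix of the same shape marking foreground.
#' @return An object of class `image2d`.
#' @export
image2d <- function(pixels, spacing = 1, mask = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(dim(pixels)) != 2L)
    stop("pixels must be a 2D numeric matrix")
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number (mm)")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(pixels)))
      stop("mask shape must match pixels")
    storage.mode(mask) <- "logical"
  }
  structure(list(pixels = pixels, spacing = spacing, mask = mask),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, spacing %g mm, range [%g, %g]%s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing,
              min(x$pixels), max(x$pixels),
              if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' Rescale intensities linearly to \[0, 255\]
#'
#' Constant images map to 0 (the degenerate range is handled by convention
#' rather than dividing by zero).
#'
#' @param x numeric matrix or vector.
#' @return Rescaled object of the same shape.
#' @export
rescale_intensities <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Read a 2D grayscale image
#'
#' Supports PNG, TIFF and single-slice NIfTI. Intensities are linearly
#' rescaled to \[0, 255\] on ingest; the pixel spacing (mm) is attached.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param spacing_mm pixel size in mm. For NIfTI, defaults to the header
#'   spacing when `NULL`.
#' @return An [image2d].
#' @export
read_image <- function(path, spacing_mm = 1) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(sub("^.*\\.(?=[a-zA-Z]+$)", "", sub("\\.gz$", "", path),
                     perl = TRUE))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path)
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    px <- as.array(img)
    px <- drop(px)
    if (is.null(spacing_mm)) spacing_mm <- RNifti::pixdim(img)[1]
  } else {
    stop("unsupported image format: ", ext)
  }
  px <- drop(px)
  if (length(dim(px)) != 2L)
    stop("image is not a 2D grayscale raster (got ",
         paste(dim(px), collapse = "x"), ")")
  if (is.null(spacing_mm)) spacing_mm <- 1
  image2d(rescale_intensities(px), spacing = spacing_mm)
}

#' Write a 2D image
#'
#' PNG/TIFF output stores intensities scaled from \[0, 255\] to \[0, 1\]
#' (8-bit for PNG); NIfTI stores raw float intensities and the spacing.
#'
#' @param img an [image2d].
#' @param path destination (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  ext <- tolower(sub("^.*\\.(?=[a-zA-Z]+$)", "", sub("\\.gz$", "", path),
                     perl = TRUE))
  if (ext == "png") {
    png::writePNG(pmin(pmax(img$pixels / 255, 0), 1), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pmin(pmax(img$pixels / 255, 0), 1), path,
                    bits.per.sample = 16L)
  } else if (ext == "nii") {
    nim <- RNifti::asNifti(img$pixels)
    RNifti::pixdim(nim) <- c(img$spacing, img$spacing)
    RNifti::writeNifti(nim, path, datatype = "double")
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Landmarks
# ---------------------------------------------------------------------------

#' Paired landmark set
#'
#' Corresponding manually (or synthetically) placed points in the MRI and
#' histology images, in mm, with the isotropic Gaussian placement error
#' standard deviation `sigma_k`.
#'
#' @param mri n x 2 matrix of (x, y) positions in the MRI image (mm).
#' @param hist n x 2 matrix of (x, y) positions in the histology image (mm).
#' @param sigma_k landmark placement standard deviation in mm (> 0).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(mri = matrix(numeric(0), 0, 2),
                         hist = matrix(numeric(0), 0, 2),
                         sigma_k = 0.5) {
  mri <- matrix(as.numeric(mri), ncol = 2)
  hist <- matrix(as.numeric(hist), ncol = 2)
  if (nrow(mri) != nrow(hist)) stop("mri and hist must pair up row-wise")
  if (sigma_k <= 0) stop("sigma_k must be > 0")
  structure(list(mri = mri, hist = hist, sigma_k = sigma_k),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d pairs, sigma_k = %g mm\n",
              nrow(x$mri), x$sigma_k))
  invisible(x)
}

#' @export
length.landmark_set <- function(x) nrow(x$mri)

#' Read landmark pairs from CSV
#'
#' Expects a header `x_mri,y_mri,x_hist,y_hist` with coordinates in mm.
#' Pairs falling outside a supplied image domain are dropped with a warning.
#'
#' @param path CSV file path.
#' @param sigma_k placement standard deviation (mm) to attach.
#' @param domain optional [image2d] (or anything with `dim` + `$spacing`)
#'   used to validate that points fall inside the image extent.
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path, sigma_k = 0.5, domain = NULL) {
  tab <- read.csv(path)
  need <- c("x_mri", "y_mri", "x_hist", "y_hist")
  if (!all(need %in% names(tab)))
    stop("landmark table must have columns ", paste(need, collapse = ", "))
  mri <- cbind(tab$x_mri, tab$y_mri)
  hst <- cbind(tab$x_hist, tab$y_hist)
  if (!is.null(domain) && nrow(mri) > 0) {
    ext <- (dim(domain)[2:1] - 1) * domain$spacing  # (x extent, y extent)
    inside <- function(p) p[, 1] >= 0 & p[, 1] <= ext[1] &
      p[, 2] >= 0 & p[, 2] <= ext[2]
    keep <- inside(mri) & inside(hst)
    if (any(!keep)) {
      warning(sum(!keep), " landmark pair(s) outside the image domain; dropped")
      mri <- mri[keep, , drop = FALSE]
      hst <- hst[keep, , drop = FALSE]
    }
  }
  landmark_set(mri, hst, sigma_k = sigma_k)
}

#' Write landmark pairs to CSV
#'
#' Round trips with [read_landmarks] losslessly to 6 decimals.
#'
#' @param lm a [landmark_set].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  tab <- data.frame(x_mri = round(lm$mri[, 1], 6),
                    y_mri = round(lm$mri[, 2], 6),
                    x_hist = round(lm$hist[, 1], 6),
                    y_hist = round(lm$hist[, 2], 6))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Deformation fields
# ---------------------------------------------------------------------------

#' Dense 2D displacement field
#'
#' Displacement vectors in mm on the histology-space pixel grid; channel
#' order is (dx, dy).
#'
#' @param dx,dy numeric matrices of x/y displacements (mm).
#' @param spacing pixel size in mm.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(dx, dy, spacing = 1) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!identical(dim(dx), dim(dy))) stop("dx and dy shapes must match")
  if (!all(is.finite(dx)) || !all(is.finite(dy)))
    stop("displacements must be finite")
  if (spacing <= 0) stop("spacing must be > 0")
  structure(list(dx = dx, dy = dy, spacing = spacing),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf("<deformation_field> %d x %d px, spacing %g mm, |u| max %.3g mm\n",
              nrow(x$dx), ncol(x$dx), x$spacing, max(mag)))
  invisible(x)
}

#' @export
dim.deformation_field <- function(x) dim(x$dx)

#' Read/write displacement fields (NIfTI, two channels, mm)
#'
#' Fields are stored as H x W x 2 float NIfTI volumes, channels (dx, dy) in
#' mm, with pixel spacing in the header. The round trip is lossless.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return [read_field] returns a [deformation_field].
#' @export
read_field <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L || dim(arr)[3] != 2L)
    stop("field file must have exactly two channels (dx, dy)")
  sp <- RNifti::pixdim(RNifti::readNifti(path))[1]
  deformation_field(arr[, , 1], arr[, , 2], spacing = sp)
}

#' @rdname read_field
#' @param field a [deformation_field].
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "deformation_field"))
  arr <- array(c(field$dx, field$dy), dim = c(dim(field$dx), 2L))
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- c(field$spacing, field$spacing, 1)
  RNifti::writeNifti(nim, path, datatype = "double")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration
# ---------------------------------------------------------------------------

#' Model and algorithm configuration
#'
#' Default values are the reference settings of the method: MRF weights
#' `beta1 = beta2 = 0.02` (the unary weight corresponds to a displacement
#' prior scale of about 5 mm), landmark standard deviation
#' `sigma_k = 0.5` mm, Inverse-Gamma variance prior `a = 2`,
#' `b = 25 * a = 50` (four pseudo-observations with sample variance 25),
#' 100 trees with at least 5 samples per leaf and 5 candidate split
#' features (the square root of the 32 features), 64 mutual-information
#' bins, B-spline regulariser weights `beta_b = 0.001`, `beta_l = 0.01`,
#' `beta_j = 0`, and a displacement label grid of radius 10 mm in 0.5 mm
#' steps. The image-term weight of the B-spline objective is
#' `alpha = 2 / (9 |Omega|)`, computed from the image size at run time.
#'
#' @param ... named overrides of any default.
#' @return An object of class `reg_config` (a named list).
#' @export
reg_config <- function(...) {
  cfg <- list(
    beta1 = 0.02,            # MRF unary weight (1/mm^2)
    beta2 = 0.02,            # MRF pairwise weight (1/mm^2)
    sigma_k = 0.5,           # landmark placement std (mm)
    a = 2,                   # Inv-Gamma shape
    b = 50,                  # Inv-Gamma scale (= 5^2 * a)
    n_trees = 100,           # forest size
    min_leaf = 5,            # minimum samples per leaf
    n_split_features = 5,    # features sampled per split (~sqrt(32))
    mi_bins = 64,            # joint-histogram bins for MI
    beta_b = 0.001,          # bending-energy weight
    beta_l = 0.01,           # stretch/shear (linear-elastic) weight
    beta_j = 0,              # log-Jacobian weight
    label_radius = 10,       # displacement grid radius (mm)
    label_step = 0.5,        # displacement grid step (mm)
    cp_spacing = 6,          # control-point spacing, proposed method (mm)
    cp_spacing_mi = 18,      # control-point spacing, MI baseline (mm)
    outer_tol = 1e-2,        # relative L2 change of mu map
    max_outer = 10,          # VEM outer iterations
    inner_tol = 1e-4,        # per-pixel L1 change of q
    max_inner = 50,          # fixed-point sweeps per E-step
    seed = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  with(cfg, {
    if (beta1 < 0 || beta2 < 0 || beta_b < 0 || beta_l < 0 || beta_j < 0)
      stop("all weights must be >= 0")
    if (sigma_k <= 0) stop("sigma_k must be > 0")
    if (label_radius <= 0 || label_step <= 0)
      stop("label grid radius/step must be > 0")
  })
  structure(cfg, class = "reg_config")
}

#' @export
print.reg_config <- function(x, ...) {
  cat("<reg_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read/write a configuration as a YAML key-value file
#'
#' @param path file path.
#' @return [read_config] returns a [reg_config].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(reg_config, vals)
}

#' @rdname read_config
#' @param cfg a [reg_config].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "reg_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Seed management: all randomness flows from one integer seed; helpers
# derive per-component seeds deterministically and keep them below 2^31.
# ---------------------------------------------------------------------------

#' Derive a child seed from a master seed
#'
#' @param seed master integer seed.
#' @param i child index (>= 1).
#' @return An integer seed, deterministic in `(seed, i)`.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 8191) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
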