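#' @useDynLib trapcount, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm median
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `code` under `seed` and restore the caller's RNG state afterwards,
# so seeded operations do not perturb the global random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically mix a base seed with stream identifiers into a new seed
# in [0, 2^31 - 2]. Lehmer-style step; multiplier kept small so the double
# arithmetic stays exact (below 2^53).
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# ITU-R 601 luma for 3-channel arrays; pass-through for matrices.
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3L && d[3] >= 3L) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  if (length(d) == 3L && d[3] == 1L) return(img[, , 1])
  stop("unsupported image dimensions: ", paste(d, collapse = "x"))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Tight bounding box of a logical/numeric mask; NULL if empty.
mask_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(r0 = min(idx[, 1]), r1 = max(idx[, 1]), c0 = min(idx[, 2]), c1 = max(idx[, 2]))
}

# Number of 8-connected components of a binary mask (EBImage labelling).
n_components <- function(mask) {
  if (!any(mask > 0)) return(0L)
  max(EBImage::bwlabel(EBImage::Image(matrix(as.numeric(mask > 0), nrow(mask)))))
}
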