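# Modulus for all stable hashes: largest 31-bit prime, so every derived seed
# fits in an R integer.
.HASH_MOD <- 2147483647

#' Stable string hash
#'
#' Polynomial rolling hash of a string, reduced modulo 2^31 - 1. Pure
#' arithmetic on doubles, so the value depends only on the string content and
#' is identical across platforms and sessions.
#'
#' @param s Character scalar.
#' @return Integer in `[0, 2^31 - 2]`.
#' @keywords internal
str_hash <- function(s) {
  v <- utf8ToInt(enc2utf8(s))
  h <- 17
  for (x in v) {
    h <- (h * 131 + x + 1) %% .HASH_MOD
  }
  as.integer(h)
}

#' Derive a reproducible sub-seed
#'
#' Combines a root seed with an arbitrary sequence of labels (study id, slice
#' index, candidate index, ...) into a deterministic 31-bit seed. All
#' randomness in the package flows through seeds derived this way, so no
#' global RNG state is shared between components.
#'
#' @param root Integer root seed.
#' @param ... Further atomic labels, coerced to character.
#' @return Integer seed suitable for [set.seed()].
#' @export
subseed <- function(root, ...) {
  str_hash(paste(c(format(root), vapply(list(...), format, character(1))),
                 collapse = "\x1f"))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Hash of an image's pixel content, used by the mock predictor to key its
# per-slice randomness. Values are rounded to integers first so the hash is
# insensitive to storage mode (integer vs double) but not to content.
.hash_cache <- new.env(parent = emptyenv())

hash_array <- function(a) {
  v <- round(as.numeric(a))
  n <- length(v)
  pw <- .hash_cache$pw
  if (is.null(pw) || length(pw) < n) {
    pw <- numeric(n)
    pw[1] <- 1
    if (n > 1) for (i in 2:n) pw[i] <- (pw[i - 1] * 131) %% .HASH_MOD
    .hash_cache$pw <- pw
  }
  terms <- ((v %% .HASH_MOD) * pw[seq_len(n)]) %% .HASH_MOD
  as.integer((sum(terms) %% .HASH_MOD + n) %% .HASH_MOD)
}

#' Label 8-connected components of a binary 2D mask
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in scan order of their first pixel.
#' @keywords internal
label8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- mask > 0
  lab <- matrix(0L, nr, nc)
  idx <- which(fg)
  if (!length(idx)) return(lab)
  queue <- integer(length(idx))
  cur <- 0L
  for (start in idx) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1] <- start
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      p <- queue[head]
      head <- head + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1L:1L) {
        rr <- r + dr
        if (rr < 1L || rr > nr) next
        for (dc in -1L:1L) {
          if (dr == 0L && dc == 0L) next
          c2 <- cc + dc
          if (c2 < 1L || c2 > nc) next
          q <- rr + (c2 - 1L) * nr
          if (fg[q] && lab[q] == 0L) {
            lab[q] <- cur
            tail <- tail + 1L
            queue[tail] <- q
          }
        }
      }
    }
  }
  lab
}

# Euclidean distance transform of a binary mask (distance of each foreground
# pixel to the nearest background pixel inside the image). Pixels of an
# all-foreground image have infinite distance.
dist_transform <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  d <- EBImage::distmap(m, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

# Argmax of a distance map restricted to `within`, ties broken by the
# lexicographically smallest (row, col). Near-ties within 1e-7 are treated as
# exact ties (distinct squared integer distances differ by far more).
dist_argmax <- function(dm, within) {
  sel <- which(within > 0)
  vals <- dm[sel]
  mx <- max(vals)
  cand <- sel[vals >= mx - 1e-7]
  nr <- nrow(dm)
  rows <- ((cand - 1L) %% nr) + 1L
  cols <- ((cand - 1L) %/% nr) + 1L
  o <- order(rows, cols)[1]
  c(row = rows[o], col = cols[o])
}

# Integer disc offsets of a given pixel radius (includes the centre).
disc_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

# Paint (value TRUE/FALSE) a disc of given radius centred at (row, col) into a
# logical matrix, clipped to the image bounds.
paint_disc <- function(mask, row, col, radius, value = TRUE) {
  off <- disc_offsets(radius)
  rr <- row + off$dr
  cc <- col + off$dc
  ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  mask[cbind(rr[ok], cc[ok])] <- value
  mask
}

# Shift a binary matrix by (dr, dc), padding with background.
shift_mask <- function(mask, dr, dc) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(src_r) < 1 || length(src_c) < 1) return(out)
  out[src_r + dr, src_c + dc] <- mask[src_r, src_c] > 0
  out
}

# Binary dilation / erosion with a disc brush of pixel radius r (r = 0 is the
# identity). EBImage brushes are odd-sized; radius r maps to size 2r + 1.
morph_disc <- function(mask, r, op = c("dilate", "erode")) {
  op <- match.arg(op)
  if (r <= 0) return(mask > 0)
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  k <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  out <- if (op == "dilate") EBImage::dilate(m, k) else EBImage::erode(m, k)
  matrix(as.numeric(out), nrow(mask), ncol(mask)) > 0
}

# round-half-up to the nearest integer (0.5 always rounds away from zero for
# the nonnegative intensities handled here)
round_half_up <- function(x) floor(x + 0.5)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
}
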