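# Superposition, RMSD/RMSF and the dynamic cross-correlation matrix.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile[selection, ]` onto `reference[selection, ]`.
#'
#' @param mobile,reference N x 3 coordinate matrices (Angstrom)
#' @param selection integer atom indices used for the fit (default all)
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   transform is `x %*% R + t`), `rmsd` (Angstrom over the selection) and
#'   `transformed` (all mobile atoms transformed)
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3)
    stop("superposition needs at least 3 selected atoms")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity: rank of the centered selection must be >= 2
  if (sum(svd(A0)$d > 1e-8 * max(1, max(abs(A0)))) < 2)
    stop("selected atoms are collinear; superposition is degenerate")
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)            # x %*% R rotates mobile onto reference
  t_vec <- cb - ca %*% R
  fitted <- sweep(mobile %*% R, 2, as.numeric(t_vec), `+`)
  dev <- fitted[selection, , drop = FALSE] - B
  list(rotation = R, translation = as.numeric(t_vec),
       rmsd = sqrt(mean(rowSums(dev^2))), transformed = fitted)
}

rmsd_pair <- function(a, b, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(a))
  d <- a[selection, , drop = FALSE] - b[selection, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' Each frame is superposed onto the reference over `fit_selection` (defaults
#' to `selection`) before the RMSD over `selection` is measured, mirroring the
#' usual "C-alpha RMSD from the starting structure" stability trace.
#'
#' @param traj an `md_trajectory`
#' @param reference N x 3 reference coordinates
#' @param selection atom indices entering the RMSD (default all)
#' @param fit_selection atom indices used for the superposition
#' @param superpose_frames superpose before measuring? (default TRUE)
#' @return numeric vector, one non-negative value per frame (Angstrom), with
#'   attribute `mean`
#' @export
rmsd_series <- function(traj, reference, selection = NULL,
                        fit_selection = selection, superpose_frames = TRUE) {
  reference <- as.matrix(reference)
  F_ <- n_frames(traj)
  out <- numeric(F_)
  for (i in seq_len(F_)) {
    fr <- frame_coords(traj, i)
    if (superpose_frames) {
      fit <- superpose(fr, reference,
                       if (is.null(fit_selection)) NULL else fit_selection)
      fr <- fit$transformed
    }
    out[i] <- rmsd_pair(fr, reference, selection)
  }
  attr(out, "mean") <- mean(out)
  out
}

# Superpose all frames onto a reference; returns F x N x 3 array.
superpose_frames_onto <- function(traj, reference, fit_selection = NULL) {
  F_ <- n_frames(traj)
  out <- array(0, dim = dim(traj$frames))
  for (i in seq_len(F_)) {
    fr <- frame_coords(traj, i)
    out[i, , ] <- superpose(fr, reference, fit_selection)$transformed
  }
  out
}

# Iterated mean-structure reference: superpose onto frame 1, take the mean,
# then superpose onto that mean (twice) - standard practice for RMSF/DCCM.
mean_structure_fit <- function(traj, fit_selection = NULL, iterations = 2) {
  ref <- frame_coords(traj, 1)
  frames <- traj$frames
  for (k in seq_len(iterations)) {
    frames <- superpose_frames_onto(trajectory(frames, traj$frame_interval),
                                    ref, fit_selection)
    ref <- apply(frames, c(2, 3), mean)
  }
  list(frames = frames, mean = ref)
}

#' Root mean square fluctuation per selected atom
#'
#' Frames are superposed onto the (iterated) mean structure first, so RMSF is
#' invariant to rigid motion of whole frames. RMSF_i =
#' sqrt(< |r_i - <r_i>|^2 >).
#'
#' @param traj an `md_trajectory`
#' @param selection atom indices to report (default all)
#' @param fit_selection atom indices used for superposition (default
#'   `selection`)
#' @param superpose_frames set FALSE if frames are already aligned
#' @return numeric vector of fluctuations (Angstrom), named by selection index
#' @export
rmsf <- function(traj, selection = NULL, fit_selection = selection,
                 superpose_frames = TRUE) {
  if (is.null(selection)) selection <- seq_len(dim(traj$frames)[2])
  frames <- if (superpose_frames)
    mean_structure_fit(traj, fit_selection)$frames else traj$frames
  sub <- frames[, selection, , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  F_ <- dim(sub)[1]
  dev2 <- 0
  for (i in seq_len(F_)) {
    d <- matrix(sub[i, , ], ncol = 3) - mu
    dev2 <- dev2 + rowSums(d^2)
  }
  out <- sqrt(dev2 / F_)
  names(out) <- selection
  out
}

#' Dynamic cross-correlation matrix
#'
#' Normalised covariance of positional fluctuations,
#' c_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>), over the selected atoms
#' (conventionally the C-alpha set). +1 is fully correlated motion, -1 fully
#' anti-correlated. Atoms with zero variance get zero off-diagonal entries and
#' a unit diagonal (with a warning) rather than NaNs.
#'
#' @param traj an `md_trajectory` with >= 2 frames
#' @param selection atom indices entering the matrix (default all)
#' @param fit_selection atom indices for superposition (default `selection`)
#' @param superpose_frames superpose onto the mean structure first
#'   (default TRUE)
#' @param labels optional residue labels for rows/columns
#' @return object of class `correlation_matrix`: the n x n matrix with
#'   `labels` attribute
#' @export
dccm <- function(traj, selection = NULL, fit_selection = selection,
                 superpose_frames = TRUE, labels = NULL) {
  if (n_frames(traj) < 2) stop("dccm needs at least 2 frames")
  if (is.null(selection)) selection <- seq_len(dim(traj$frames)[2])
  frames <- if (superpose_frames)
    mean_structure_fit(traj, fit_selection)$frames else traj$frames
  sub <- frames[, selection, , drop = FALSE]
  F_ <- dim(sub)[1]; n <- dim(sub)[2]
  mu <- apply(sub, c(2, 3), mean)
  # cross products accumulated per coordinate axis: C = sum_axis cov(axis)
  C <- matrix(0, n, n)
  for (ax in 1:3) {
    X <- sub[, , ax] - matrix(mu[, ax], F_, n, byrow = TRUE)
    C <- C + crossprod(X) / F_
  }
  v <- diag(C)
  zero <- v <= 0 | !is.finite(v)
  if (any(zero)) {
    warning(sum(zero), " zero-variance atom(s) in dccm; rows/columns zeroed")
    v[zero] <- 1
  }
  M <- C / sqrt(outer(v, v))
  if (any(zero)) {
    M[zero, ] <- 0
    M[, zero] <- 0
  }
  M <- (M + t(M)) / 2
  M[M > 1] <- 1; M[M < -1] <- -1
  diag(M) <- 1
  if (is.null(labels)) labels <- as.character(selection)
  dimnames(M) <- list(labels, labels)
  structure(M, class = c("correlation_matrix", "matrix"), labels = labels)
}

#' Parse a named region specification
#'
#' Regions are inclusive residue ranges in author (1-based) numbering, given
#' as `"start-end"` strings, e.g. `list(R1 = "122-131", loops = "51-58")`.
#'
#' @param spec named list/vector of `"start-end"` strings (or length-2
#'   numeric vectors)
#' @return data.frame with columns name, start, end
#' @export
region_spec <- function(spec) {
  stopifnot(length(names(spec)) == length(spec))
  parse1 <- function(x) {
    if (is.numeric(x) && length(x) == 2) return(as.integer(x))
    m <- regmatches(x, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", x))[[1]]
    if (length(m) != 3) stop("bad region range: ", x)
    as.integer(m[2:3])
  }
  rng <- t(vapply(spec, parse1, integer(2)))
  if (any(rng[, 2] < rng[, 1])) stop("region end before start")
  data.frame(name = names(spec), start = rng[, 1], end = rng[, 2],
             stringsAsFactors = FALSE)
}

# Default fluctuation regions: the loop/turn stretches whose mobility drops on
# binding, plus the C-terminal beta-strand block R1 (122-131).
#' @rdname region_spec
#' @export
default_regions <- function() {
  region_spec(list(R1 = "122-131", F1 = "8-21", F2 = "32-36", F3 = "51-58",
                   F4 = "86-94", F5 = "105-115", F6 = "120-123"))
}

#' Per-region summary of an RMSF profile or correlation matrix
#'
#' For vector input (RMSF keyed by residue id) the per-region statistic is the
#' mean over residues in the range. For a `correlation_matrix` it is the mean
#' off-diagonal correlation within the region's block. With a second input,
#' signed differences `b - a` per region are added (bound-vs-unbound style
#' comparisons).
#'
#' @param a RMSF vector named by residue id, or a `correlation_matrix` whose
#'   labels are residue ids
#' @param regions a data.frame from [region_spec()]
#' @param b optional second input of the same shape
#' @return data.frame with columns name, mean_a (and mean_b, difference)
#' @export
region_summary <- function(a, regions, b = NULL) {
  stat1 <- function(x, start, end) {
    if (inherits(x, "correlation_matrix")) {
      ids <- as.integer(attr(x, "labels"))
      sel <- which(ids >= start & ids <= end)
      if (!length(sel)) stop("region ", start, "-", end,
                             " outside the residue span")
      blk <- unclass(x)[sel, sel, drop = FALSE]
      if (length(sel) == 1) return(blk[1, 1])
      mean(blk[upper.tri(blk)])
    } else {
      ids <- as.integer(names(x))
      sel <- which(ids >= start & ids <= end)
      if (!length(sel)) stop("region ", start, "-", end,
                             " outside the residue span")
      mean(x[sel])
    }
  }
  out <- data.frame(name = regions$name,
                    mean_a = mapply(stat1, regions$start, regions$end,
                                    MoreArgs = list(x = a)))
  if (!is.null(b)) {
    out$mean_b <- mapply(stat1, regions$start, regions$end,
                         MoreArgs = list(x = b))
    out$difference <- out$mean_b - out$mean_a
  }
  out
}

#' Write a correlation matrix as TSV (labels as header row/column)
#' @param m a `correlation_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dccm <- function(m, path) {
  tab <- cbind(residue = attr(m, "labels"), as.data.frame(unclass(m)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
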