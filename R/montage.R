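#' Idealized 10-10 EEG montage on the unit sphere
#'
#' Builds a 63-channel 10-10 montage (61 standard channels plus O1/O2) with
#' electrode positions on the unit sphere, generated from the standard
#' proportional placement scheme: midline electrodes lie on the
#' nasion-inion great circle at 10%-of-arc steps, the outer ring lies on
#' the 10% circumference circle, and intermediate electrodes are placed by
#' great-circle (slerp) interpolation between the midline electrode of a
#' row and the corresponding ring electrode.
#'
#' Coordinate convention: x = right, y = anterior, z = superior; all
#' positions have unit norm.
#'
#' The montage carries the named channel subsets used throughout the
#' analysis:
#' \describe{
#'   \item{analysis}{28 fronto-central/centro-parietal channels over which
#'     peak CKC is measured (Fz/F1-F6, FCz/FC1-FC6, Cz/C1-C6, CPz/CP1-CP6).}
#'   \item{cv}{midline and centro-parietal channels (F, FC, C, CP and P
#'     rows) used for leave-one-out cross-validation of the CSD
#'     regularization constant.}
#'   \item{left, right}{12-channel lateralized sets used for the
#'     contra/ipsilateral coherence contrast.}
#' }
#'
#' @return An object of class \code{ckc_montage}: a list with \code{labels}
#'   (character), \code{positions} (n x 3 matrix, rownames = labels) and
#'   \code{subsets} (named list of character vectors).
#' @export
ckc_montage <- function() {
  deg <- pi / 180

  ## midline: polar angle from vertex along the sagittal great circle
  mid_labels <- c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz")
  mid_theta  <- c(72, 54, 36, 18, 0, -18, -36, -54, -72) * deg # + = anterior
  mid_pos <- cbind(0, sin(mid_theta), cos(mid_theta))
  rownames(mid_pos) <- mid_labels

  ## outer ring: 72 deg from vertex, azimuth measured from anterior midline
  ring_labels_l <- c("Fp1", "AF7", "F7", "FT7", "T7", "TP7", "P7", "PO7", "O1")
  ring_alpha    <- seq(18, 162, by = 18) * deg
  ring_pos_l <- cbind(-sin(72 * deg) * sin(ring_alpha),
                      sin(72 * deg) * cos(ring_alpha),
                      cos(72 * deg))
  rownames(ring_pos_l) <- ring_labels_l

  slerp <- function(p, q, f) {
    om <- acos(pmin(1, pmax(-1, sum(p * q))))
    v <- (sin((1 - f) * om) * p + sin(f * om) * q) / sin(om)
    v / sqrt(sum(v^2))
  }

  ## inner rows: fractions along the arc midline -> ring electrode
  rows <- list(
    AF = list(mid = "AFz", ring = "AF7", lab = c("AF3"),             f = 0.5),
    F  = list(mid = "Fz",  ring = "F7",  lab = c("F1", "F3", "F5"),  f = c(0.25, 0.5, 0.75)),
    FC = list(mid = "FCz", ring = "FT7", lab = c("FC1", "FC3", "FC5"), f = c(0.25, 0.5, 0.75)),
    C  = list(mid = "Cz",  ring = "T7",  lab = c("C1", "C3", "C5"),  f = c(0.25, 0.5, 0.75)),
    CP = list(mid = "CPz", ring = "TP7", lab = c("CP1", "CP3", "CP5"), f = c(0.25, 0.5, 0.75)),
    P  = list(mid = "Pz",  ring = "P7",  lab = c("P1", "P3", "P5"),  f = c(0.25, 0.5, 0.75)),
    PO = list(mid = "POz", ring = "PO7", lab = c("PO3"),             f = 0.5)
  )
  inner_lab <- character(0); inner_pos <- NULL
  for (rw in rows) {
    for (k in seq_along(rw$lab)) {
      p <- slerp(mid_pos[rw$mid, ], ring_pos_l[rw$ring, ], rw$f[k])
      inner_pos <- rbind(inner_pos, p)
      inner_lab <- c(inner_lab, rw$lab[k])
    }
  }
  rownames(inner_pos) <- inner_lab

  ## TP9: 18 deg below the ring at the TP7 azimuth
  tp9 <- c(-sin(90 * deg) * sin(108 * deg),
           sin(90 * deg) * cos(108 * deg),
           cos(90 * deg))

  mirror <- function(pos) cbind(-pos[, 1, drop = FALSE], pos[, 2:3, drop = FALSE])
  mirror_label <- function(lab) {
    num <- as.integer(sub("^[A-Za-z]+", "", lab))
    paste0(sub("[0-9]+$", "", lab), num + 1L)
  }

  left_lab <- c(ring_labels_l, inner_lab, "TP9")
  left_pos <- rbind(ring_pos_l, inner_pos, TP9 = tp9)
  right_lab <- unname(vapply(left_lab, mirror_label, character(1)))
  right_pos <- mirror(left_pos)
  rownames(right_pos) <- right_lab

  labels <- c(mid_labels, left_lab, right_lab)
  positions <- rbind(mid_pos, left_pos, right_pos)
  rownames(positions) <- labels

  subsets <- list(
    analysis = c("Fz", paste0("F", 1:6), "FCz", paste0("FC", 1:6),
                 "Cz", paste0("C", 1:6), "CPz", paste0("CP", 1:6)),
    cv = c("Fz", paste0("F", 1:6), "FCz", paste0("FC", 1:6),
           "Cz", paste0("C", 1:6), "CPz", paste0("CP", 1:6),
           "Pz", paste0("P", 1:6)),
    left  = c("F5", "F3", "F1", "FC5", "FC3", "FC1",
              "C5", "C3", "C1", "CP5", "CP3", "CP1"),
    right = c("F2", "F4", "F6", "FC2", "FC4", "FC6",
              "C2", "C4", "C6", "CP2", "CP4", "CP6")
  )
  stopifnot(all(unlist(subsets) %in% labels))

  structure(list(labels = labels, positions = positions, subsets = subsets),
            class = "ckc_montage")
}

#' Restrict a montage to a subset of channels
#'
#' @param montage a \code{ckc_montage}
#' @param labels channels to keep, in montage order
#' @return a \code{ckc_montage} containing only \code{labels}
#' @export
montage_subset <- function(montage, labels) {
  missing <- setdiff(labels, montage$labels)
  if (length(missing))
    stop("unknown channel label(s): ", paste(missing, collapse = ", "))
  keep <- montage$labels[montage$labels %in% labels]
  structure(list(labels = keep,
                 positions = montage$positions[keep, , drop = FALSE],
                 subsets = lapply(montage$subsets, intersect, x = keep)),
            class = "ckc_montage")
}

#' @export
print.ckc_montage <- function(x, ...) {
  cat("<ckc_montage> ", length(x$labels), " channels; subsets: ",
      paste(sprintf("%s(%d)", names(x$subsets), lengths(x$subsets)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
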