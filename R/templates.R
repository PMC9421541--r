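#' Planar electrode coordinates for the 10-20 system
#'
#' Approximate 2D projections (x: left -1 to right +1, y: posterior -1 to
#' anterior +1) of the 19 standard 10-20 electrodes, plus the alternative
#' temporal names (T7/T8/P7/P8 for T3/T4/T5/T6).
#'
#' @param labels channel labels to look up.
#' @return Matrix with columns `x`, `y`, one row per label.
#' @export
montage_1020_positions <- function(labels) {
  pos <- rbind(
    Fp1 = c(-0.31,  0.95), Fp2 = c( 0.31,  0.95),
    F7  = c(-0.81,  0.59), F3  = c(-0.52,  0.53), Fz = c(0,  0.50),
    F4  = c( 0.52,  0.53), F8  = c( 0.81,  0.59),
    T3  = c(-1.00,  0.00), C3  = c(-0.50,  0.00), Cz = c(0,  0.00),
    C4  = c( 0.50,  0.00), T4  = c( 1.00,  0.00),
    T5  = c(-0.81, -0.59), P3  = c(-0.52, -0.53), Pz = c(0, -0.50),
    P4  = c( 0.52, -0.53), T6  = c( 0.81, -0.59),
    O1  = c(-0.31, -0.95), O2  = c( 0.31, -0.95))
  alias <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  canon <- ifelse(labels %in% names(alias), alias[labels], labels)
  unknown <- setdiff(canon, rownames(pos))
  if (length(unknown) > 0L) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  }
  out <- pos[canon, , drop = FALSE]
  dimnames(out) <- list(labels, c("x", "y"))
  out
}

#' Standard 19-channel 10-20 montage labels
#' @return Character vector of 19 labels.
#' @export
montage_1020_19 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Canonical microstate template maps A-E
#'
#' Builds the five prototypical microstate topographies on a given montage:
#' A and B are the mirror-image diagonal gradients (A: left-posterior
#' positive to right-anterior negative, B: right-posterior to left-anterior),
#' C is an anterior-posterior gradient, D has a fronto-central maximum and
#' E a centro-posterior maximum. Each map is average-referenced and scaled to
#' unit L2 norm; the set is deterministic for a given montage.
#'
#' @param n_channels number of channels (must match `montage` length).
#' @param montage channel labels, standard 10-20 names.
#' @return A [ms_mapset] of 5 maps labeled A-E, level `"template"`.
#' @export
make_canonical_templates <- function(n_channels = 19L,
                                     montage = montage_1020_19()) {
  if (length(montage) != n_channels) {
    stop("montage length does not match n_channels")
  }
  p <- montage_1020_positions(montage)
  x <- p[, "x"]; y <- p[, "y"]
  bump <- function(cx, cy, s) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
  maps <- rbind(
    A = -(x + y) / 2,              # left-posterior (+) / right-anterior (-)
    B = (x - y) / 2,               # right-posterior (+) / left-anterior (-)
    C = y,                         # anterior (+) / posterior (-)
    D = bump(0, 0.35, 0.45),       # fronto-central maximum
    E = bump(0, -0.40, 0.45))      # centro-posterior maximum
  maps <- normalize_rows(maps)
  colnames(maps) <- montage
  ms_mapset(maps, labels = rownames(maps), level = "template",
            channel_labels = montage)
}
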