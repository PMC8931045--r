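#' Electrode layout
#'
#' A channel layout names each electrode and places it on the unit disc
#' (top view of the scalp, nose up, dimensionless coordinates). Layouts drive
#' the large-Laplacian neighbour search, the simulator's forward model and
#' topographic rendering.
#'
#' @param names Character vector of unique channel identifiers.
#' @param positions Numeric matrix with one row per channel and columns
#'   `x`, `y` (left-right, posterior-anterior) on the unit disc.
#' @return An object of class `ChannelLayout` with fields `names` and
#'   `positions`.
#' @examples
#' lay <- channel_layout(c("C3", "Cz", "C4"),
#'                       rbind(c(-0.4, 0), c(0, 0), c(0.4, 0)))
#' @export
channel_layout <- function(names, positions) {
  names <- as.character(names)
  positions <- as.matrix(positions)
  if (anyDuplicated(names)) {
    stop("channel names must be unique; duplicated: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (nrow(positions) != length(names) || ncol(positions) != 2) {
    stop("positions must be a ", length(names), " x 2 matrix")
  }
  if (!all(is.finite(positions))) stop("positions must be finite")
  storage.mode(positions) <- "double"
  dimnames(positions) <- list(names, c("x", "y"))
  structure(list(names = names, positions = positions),
            class = "ChannelLayout")
}

#' @export
print.ChannelLayout <- function(x, ...) {
  cat("<ChannelLayout> ", length(x$names), " channels: ",
      paste(utils::head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

n_channels <- function(layout) length(layout$names)

#' Standard 22-channel sensorimotor montage
#'
#' The 22-electrode 10-20 montage covering the sensorimotor strip
#' (Fz, FC row, C row, CP row, P row, POz), projected onto the unit disc.
#' Left/right hemisphere positions are mirror-symmetric about the midline.
#'
#' @return A [channel_layout()] with 22 channels.
#' @export
default_layout_22 <- function() {
  pos <- rbind(
    Fz  = c( 0.00,  0.60),
    FC3 = c(-0.35,  0.35), FC1 = c(-0.12,  0.35), FCz = c(0.00, 0.35),
    FC2 = c( 0.12,  0.35), FC4 = c( 0.35,  0.35),
    C5  = c(-0.60,  0.00), C3  = c(-0.37,  0.00), C1  = c(-0.12, 0.00),
    Cz  = c( 0.00,  0.00), C2  = c( 0.12,  0.00), C4  = c( 0.37, 0.00),
    C6  = c( 0.60,  0.00),
    CP3 = c(-0.35, -0.35), CP1 = c(-0.12, -0.35), CPz = c(0.00, -0.35),
    CP2 = c( 0.12, -0.35), CP4 = c( 0.35, -0.35),
    P1  = c(-0.12, -0.60), Pz  = c( 0.00, -0.60), P2  = c(0.12, -0.60),
    POz = c( 0.00, -0.85)
  )
  channel_layout(rownames(pos), pos)
}
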