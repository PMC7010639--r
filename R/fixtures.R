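#' Synthetic channel layout
#'
#' 2D topography coordinates for the default 102-channel magnetometer grid,
#' generated as a sunflower (golden-angle) spiral on the unit disk. This is a
#' synthetic stand-in layout for plotting and channel-subset selection; it is
#' not a vendor sensor geometry.
#'
#' @param n_channels number of channels.
#' @return data.frame with columns `id`, `x2d`, `y2d`.
#' @export
channel_layout <- function(n_channels = 102) {
  i <- seq_len(n_channels)
  r <- sqrt((i - 0.5) / n_channels)
  theta <- i * 2.399963229728653  # golden angle
  data.frame(id = sprintf("MAG%03d", i),
             x2d = r * cos(theta), y2d = r * sin(theta))
}

#' Synthetic parcellation label table
#'
#' Area labels for area-level ("source-level") analyses: 180 areas per
#' hemisphere plus one unassigned collection per hemisphere, 362 rows total.
#' Labels are synthetic generic codes standing in for a cortical atlas; the
#' statistics only need the grid size and hemisphere bookkeeping.
#'
#' @param n_areas_per_hemisphere named areas per hemisphere.
#' @return data.frame with columns `area`, `hemisphere` ("L"/"R").
#' @export
parcellation_labels <- function(n_areas_per_hemisphere = 180) {
  per_hemi <- c(sprintf("A%03d", seq_len(n_areas_per_hemisphere)), "unassigned")
  data.frame(area = rep(per_hemi, 2),
             hemisphere = rep(c("L", "R"), each = length(per_hemi)))
}
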