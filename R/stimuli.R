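# Stimulus module: the nine canonical flicker frequency sets, checkerboard
# raster rendering (squares and 1-3 layer flickering circles), per-frame
# flicker schedules for a given display refresh rate, and the 3 x 3 on-screen
# layout.

#' Canonical flicker frequency table
#'
#' The nine flicker stimuli used to encode six commands: three single
#' fundamental frequencies (SFF), three fundamentals mixed with a harmonic or
#' subharmonic (MFH), and three pairs of fundamentals (MFF). Commands 1-3 are
#' encoded by the fundamental (7, 13, 17 Hz; reachable through either the SFF
#' or the MFH stimulus of that fundamental), commands 4-6 by the unordered
#' pair of fundamentals of an MFF stimulus.
#'
#' @return A data frame with one row per stimulus, in canonical presentation
#'   order, and columns:
#'   \describe{
#'     \item{symbol}{`SFF1..3`, `MFH1..3`, `MFF1..3`.}
#'     \item{condition}{Flicker condition, `"SFF"`, `"MFH"` or `"MFF"`.}
#'     \item{sequence}{Presentation order 1-9.}
#'     \item{f1}{First fundamental (Hz).}
#'     \item{f2}{Second fundamental (Hz), `NA` unless MFF.}
#'     \item{fh}{Harmonic or subharmonic companion (Hz), `NA` unless MFH.}
#'     \item{command_id}{Command 1-6 the stimulus encodes.}
#'   }
#' @examples
#' flicker_table()
#' @export
flicker_table <- function() {
  data.frame(
    symbol = c("SFF1", "SFF2", "SFF3", "MFH1", "MFH2", "MFH3",
               "MFF1", "MFF2", "MFF3"),
    condition = rep(c("SFF", "MFH", "MFF"), each = 3L),
    sequence = 1:9,
    f1 = c(7, 13, 17, 7, 13, 17, 7, 7, 13),
    f2 = c(NA, NA, NA, NA, NA, NA, 13, 17, 17),
    fh = c(NA, NA, NA, 14, 6.5, 8.5, NA, NA, NA),
    command_id = c(1L, 2L, 3L, 1L, 2L, 3L, 4L, 5L, 6L),
    stringsAsFactors = FALSE
  )
}

# Resolve a stimulus given as a symbol string or a one-row slice of
# flicker_table() to its table row.
resolve_flicker <- function(stimulus) {
  tab <- flicker_table()
  if (is.character(stimulus) && length(stimulus) == 1L) {
    i <- match(stimulus, tab$symbol)
    if (is.na(i)) stop_config("unknown flicker symbol: ", stimulus)
    return(tab[i, , drop = FALSE])
  }
  if (is.data.frame(stimulus) && nrow(stimulus) == 1L) return(stimulus)
  stop_config("stimulus must be a symbol string or a one-row flicker table slice")
}

#' Component frequencies of a flicker stimulus
#'
#' The frequencies a stimulus physically flickers at: the fundamental(s), plus
#' the harmonic/subharmonic companion for MFH stimuli.
#'
#' @param stimulus Symbol string (e.g. `"MFF1"`) or one-row flicker-table slice.
#' @return Numeric vector of 1 or 2 frequencies (Hz).
#' @export
flicker_components <- function(stimulus) {
  row <- resolve_flicker(stimulus)
  out <- c(row$f1, row$f2, row$fh)
  out[!is.na(out)]
}

#' Frequencies of interest elicited by a stimulus
#'
#' The subset of the nine monitored frequencies at which an attended stimulus
#' is expected to evoke power: its component frequencies plus their second and
#' third harmonics that fall inside the frequencies-of-interest set. Used both
#' by the synthetic generator and by label-aware calibration.
#'
#' @inheritParams flicker_components
#' @param harmonics Include 2nd/3rd harmonics of each component (default TRUE).
#' @return Numeric vector, a subset of [frequencies_of_interest()] in canonical
#'   order.
#' @export
stimulus_frequencies <- function(stimulus, harmonics = TRUE) {
  comps <- flicker_components(stimulus)
  out <- comps
  if (harmonics) {
    for (k in 2:3) out <- c(out, comps * k)
  }
  FOI[FOI %in% out]
}

n_layers <- function(pattern) {
  i <- match(pattern, c("CB0", "CB1", "CB2", "CB3"))
  if (is.na(i)) stop_config("unknown checkerboard pattern: ", pattern)
  i - 1L
}

#' Flicker region map of a checkerboard pattern
#'
#' Assigns every pixel of the stimulus raster to a flickering region. `CB0`
#' (conventional flickering squares) has a single region covering the whole
#' raster; `CB1`-`CB3` place 1-3 concentric circle layers (region 1 is the
#' outermost annulus, the highest region index the central disc) on a
#' non-flickering surround (region 0).
#'
#' @param pattern `"CB0"`, `"CB1"`, `"CB2"` or `"CB3"`.
#' @param size_cm Stimulus width and height in cm (default `c(4, 5)`).
#' @param px_per_cm Raster scale; default 37.8 px/cm (96 dpi).
#' @return Integer matrix (rows = height px, cols = width px) of region ids.
#' @export
pattern_regions <- function(pattern, size_cm = c(4, 5), px_per_cm = 37.8) {
  L <- n_layers(pattern)
  w <- round(size_cm[1] * px_per_cm)
  h <- round(size_cm[2] * px_per_cm)
  if (L == 0L) return(matrix(1L, nrow = h, ncol = w))
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  R <- min(w, h) / 2
  d <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`))
  reg <- matrix(0L, nrow = h, ncol = w)
  for (l in seq_len(L)) {
    outer_r <- R * (L - l + 1) / L
    inner_r <- R * (L - l) / L
    reg[d <= outer_r & d > inner_r] <- l
  }
  reg[d == 0] <- L  # centre pixel belongs to the innermost disc
  reg
}

#' Render a checkerboard stimulus raster
#'
#' Renders the binary (two luminance level) raster of a stimulus for a given
#' on/off state of each flickering layer. Toggling a layer's state
#' contrast-reverses the checkerboard inside that layer's region and nothing
#' else; the non-flickering surround of the circle patterns is fixed at 0.
#'
#' @inheritParams pattern_regions
#' @param layer_states Logical vector, one entry per flickering layer
#'   (`CB0` has one; `CB1`-`CB3` have 1-3, outermost first).
#' @param cell_cm Checkerboard cell edge in cm (default 0.5).
#' @return Integer 0/1 matrix (rows = height px, cols = width px) with
#'   attributes `pattern` and `regions`.
#' @examples
#' on  <- render_pattern("CB0", TRUE)
#' off <- render_pattern("CB0", FALSE)
#' all(on + off == 1)  # exact complements
#' @export
render_pattern <- function(pattern, layer_states, cell_cm = 0.5,
                           size_cm = c(4, 5), px_per_cm = 37.8) {
  L <- n_layers(pattern)
  n_states <- max(1L, L)
  layer_states <- as.logical(layer_states)
  if (length(layer_states) != n_states || anyNA(layer_states)) {
    stop_config("pattern ", pattern, " needs ", n_states,
                " logical layer state(s), got ", length(layer_states))
  }
  reg <- pattern_regions(pattern, size_cm = size_cm, px_per_cm = px_per_cm)
  h <- nrow(reg)
  w <- ncol(reg)
  cell_px <- max(1L, round(cell_cm * px_per_cm))
  checker <- (outer(floor((seq_len(h) - 1) / cell_px),
                    floor((seq_len(w) - 1) / cell_px), `+`)) %% 2L
  out <- matrix(0L, nrow = h, ncol = w)
  for (l in seq_len(n_states)) {
    m <- reg == l
    out[m] <- if (layer_states[l]) checker[m] else 1L - checker[m]
  }
  structure(out, pattern = pattern, regions = reg)
}

#' Per-frame flicker schedule
#'
#' Samples each component frequency of a stimulus as a square wave on the
#' frame grid of a display. Toggle instants (every half period) are rounded to
#' the nearest frame, bounding phase error by half a frame; duty cycle is
#' within one frame of 50%.
#'
#' @inheritParams flicker_components
#' @param refresh_hz Display refresh rate; must be at least twice the highest
#'   component frequency.
#' @param duration_s Schedule length in seconds.
#' @return Logical matrix of `round(refresh_hz * duration_s)` rows (frames) and
#'   one column per component frequency (named `"<f>Hz"`); `TRUE` = normal
#'   phase, `FALSE` = contrast-reversed. Attributes: `freqs`, `refresh_hz`,
#'   `symbol`.
#' @examples
#' sched <- frame_schedule("SFF1", refresh_hz = 70, duration_s = 1)
#' colMeans(sched)  # duty cycle ~ 0.5
#' @export
frame_schedule <- function(stimulus, refresh_hz = 60, duration_s = 5) {
  row <- resolve_flicker(stimulus)
  freqs <- flicker_components(row)
  if (refresh_hz < 2 * max(freqs)) {
    stop_config("refresh rate ", refresh_hz, " Hz is below the Nyquist rate of a ",
                max(freqs), " Hz component")
  }
  n <- round(refresh_hz * duration_s)
  out <- matrix(TRUE, nrow = n, ncol = length(freqs),
                dimnames = list(NULL, paste0(freqs, "Hz")))
  if (n > 0L) {
    for (j in seq_along(freqs)) {
      toggles <- seq_len(floor(2 * freqs[j] * duration_s)) / (2 * freqs[j])
      fidx <- round(toggles * refresh_hz)     # 0-based frame of each flip
      fidx <- fidx[fidx < n]
      flips <- cumsum(tabulate(fidx + 1L, nbins = n))
      out[, j] <- flips %% 2L == 0L
    }
  }
  structure(out, freqs = freqs, refresh_hz = refresh_hz, symbol = row$symbol)
}

#' Map a flicker schedule onto pattern layers
#'
#' Distributes the component square waves of a schedule over the flickering
#' layers of a checkerboard pattern: components are assigned outermost-first
#' (f1 to the outer layer, the harmonic/second fundamental inward); layers
#' beyond the number of components repeat the first component. A single-layer
#' pattern carrying several components combines them by XOR, which preserves
#' both spectral components in the contrast signal.
#'
#' @param schedule Result of [frame_schedule()].
#' @param pattern Checkerboard pattern name, see [pattern_regions()].
#' @return Logical matrix, frames x layer states (as expected by
#'   [render_pattern()] row by row).
#' @export
assign_layers <- function(schedule, pattern) {
  L <- max(1L, n_layers(pattern))
  k <- ncol(schedule)
  if (L == 1L && k > 1L) {
    comb <- Reduce(xor, lapply(seq_len(k), function(j) schedule[, j]))
    return(matrix(comb, ncol = 1L, dimnames = list(NULL, "layer1")))
  }
  cols <- ((seq_len(L) - 1L) %% k) + 1L
  out <- schedule[, cols, drop = FALSE]
  dimnames(out) <- list(NULL, paste0("layer", seq_len(L)))
  out
}

#' Arrange the nine stimuli on screen
#'
#' Places the canonical stimuli on a 3 x 3 grid against a gray background:
#' single fundamentals on the top row, fundamental + harmonic mixtures in the
#' middle, two-fundamental mixtures at the bottom, with 6 cm row and 12 cm
#' column spacing between 4 x 5 cm stimuli. An arbitrarily ordered frequency
#' table is regrouped into this canonical arrangement.
#'
#' @param freq_table The nine canonical stimuli (any order); default
#'   [flicker_table()].
#' @param screen_px Screen raster size (width, height), default 1920 x 1080.
#' @param px_per_cm Raster scale, default 37.8 px/cm.
#' @param size_cm Stimulus size (width, height) in cm.
#' @param row_spacing_cm,col_spacing_cm Gaps between stimulus edges.
#' @return Data frame with one row per stimulus: `symbol`, `condition`, `row`,
#'   `col`, centre coordinates `x_cm`/`y_cm` (relative to screen centre,
#'   y down) and `x_px`/`y_px`, and raster size `w_px`/`h_px`.
#' @export
layout_grid <- function(freq_table = flicker_table(), screen_px = c(1920, 1080),
                        px_per_cm = 37.8, size_cm = c(4, 5),
                        row_spacing_cm = 6, col_spacing_cm = 12) {
  canon <- flicker_table()
  if (!setequal(freq_table$symbol, canon$symbol)) {
    stop_config("freq_table must contain the nine canonical stimuli")
  }
  tab <- freq_table[match(canon$symbol, freq_table$symbol), , drop = FALSE]
  row_id <- match(tab$condition, c("SFF", "MFH", "MFF"))
  col_id <- stats::ave(seq_len(nrow(tab)), row_id, FUN = seq_along)
  x_cm <- (col_id - 2) * (size_cm[1] + col_spacing_cm)
  y_cm <- (row_id - 2) * (size_cm[2] + row_spacing_cm)
  out <- data.frame(
    symbol = tab$symbol, condition = tab$condition,
    row = row_id, col = col_id,
    x_cm = x_cm, y_cm = y_cm,
    x_px = round(screen_px[1] / 2 + x_cm * px_per_cm),
    y_px = round(screen_px[2] / 2 + y_cm * px_per_cm),
    w_px = round(size_cm[1] * px_per_cm),
    h_px = round(size_cm[2] * px_per_cm),
    stringsAsFactors = FALSE
  )
  half_w <- out$w_px / 2
  half_h <- out$h_px / 2
  if (any(out$x_px - half_w < 0 | out$x_px + half_w > screen_px[1] |
          out$y_px - half_h < 0 | out$y_px + half_h > screen_px[2])) {
    stop_config("layout does not fit on the screen raster")
  }
  out
}

#' Export a stimulus layout as JSON
#'
#' @param layout Result of [layout_grid()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(layout, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
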