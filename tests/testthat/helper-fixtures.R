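# Small in-code fixtures shared across test files. All grids use the
# reference 8 mm pitch / 60 Hz; the tiny grid spans y in [-80, 392] mm so
# both targets fit.

tiny_geometry <- function(n_rows = 60, n_cols = 21, origin = c(10, 10)) {
  mat_geometry(n_rows, n_cols, cell_pitch = 8, sampling_rate = 60,
               origin_cell = origin, y_axis = "+row")
}

zero_frame <- function(g) matrix(0, g$n_rows, g$n_cols)

# force block over 1-based matrix index ranges
put_block <- function(m, rows, cols, force = 10) {
  m[rows, cols] <- force
  m
}

make_rec <- function(frames, g = tiny_geometry(), layout = target_layout(),
                     meta = list(subject = "T01", group = "control",
                                 leg = "dominant")) {
  recording(g, layout, times = (seq_along(frames) - 1) / g$sampling_rate,
            frames = frames, duration = length(frames) / g$sampling_rate,
            meta = meta)
}

# an active region in the internal representation (0-based cells)
make_region <- function(cells, forces) {
  list(cells = cells, forces = forces, n_secondary = 0L)
}

# recording with one square blob present over the given frame indices
blob_recording <- function(on_frames, n_frames, rows = 11:12, cols = 11:12,
                           force = 10, g = tiny_geometry()) {
  frames <- lapply(seq_len(n_frames), function(i) {
    m <- zero_frame(g)
    if (i %in% on_frames) m <- put_block(m, rows, cols, force)
    m
  })
  make_rec(frames, g)
}
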