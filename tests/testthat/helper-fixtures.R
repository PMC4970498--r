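# Fixtures built in code.

new_cal_for_test <- function(offset, noise) {
  felreduce:::new_calibration_set(
    offset = offset, noise = noise,
    counts = matrix(1, nrow(offset), ncol(offset)),
    mask = matrix(0, nrow(offset), ncol(offset)),
    mode = "training", train_size = 1L, n_outlier = 4)
}

single_panel_geom <- function(n = 64, res = 5000, corner_x = 0, corner_y = 0,
                              name = "p0") {
  c(sprintf("%s/min_fs = 0", name), sprintf("%s/max_fs = %d", name, n - 1),
    sprintf("%s/min_ss = 0", name), sprintf("%s/max_ss = %d", name, n - 1),
    sprintf("%s/fs = +1.0x", name), sprintf("%s/ss = +1.0y", name),
    sprintf("%s/corner_x = %g", name, corner_x),
    sprintf("%s/corner_y = %g", name, corner_y),
    sprintf("%s/res = %g", name, res))
}

# square detector centred on the beam axis (pixel-centre symmetric)
centred_geom <- function(n = 128, res = 5000) {
  parse_geometry(single_panel_geom(n, res, corner_x = -(n - 1) / 2,
                                   corner_y = -(n - 1) / 2))
}

two_panel_geom_text <- function() {
  c("a/min_fs = 0",  "a/max_fs = 63", "a/min_ss = 0", "a/max_ss = 63",
    "a/fs = +1.0x",  "a/ss = +1.0y", "a/corner_x = 0", "a/corner_y = 0",
    "a/res = 5000",
    "b/min_fs = 64", "b/max_fs = 127", "b/min_ss = 0", "b/max_ss = 63",
    "b/fs = +1.0x",  "b/ss = +1.0y", "b/corner_x = 70", "b/corner_y = 0",
    "b/res = 5000")
}

# random toy multi-panel geometry: disjoint raw slabs side by side, each with
# a random axis-aligned orientation and integer corner offset
random_toy_geom <- function(n_panels = 3, size = 16, seed = 1) {
  withr::with_seed(seed, {
    orients <- list(c("+1.0x", "+1.0y"), c("+1.0y", "+1.0x"),
                    c("-1.0x", "-1.0y"), c("-1.0y", "+1.0x"))
    lines <- character(0)
    for (k in seq_len(n_panels)) {
      o <- orients[[sample.int(length(orients), 1)]]
      cx <- sample(0:60, 1) + (k - 1) * 90
      cy <- sample(0:60, 1)
      nm <- paste0("p", k)
      lines <- c(lines,
        sprintf("%s/min_fs = %d", nm, (k - 1) * size),
        sprintf("%s/max_fs = %d", nm, k * size - 1),
        sprintf("%s/min_ss = 0", nm),
        sprintf("%s/max_ss = %d", nm, size - 1),
        sprintf("%s/fs = %s", nm, o[1]), sprintf("%s/ss = %s", nm, o[2]),
        sprintf("%s/corner_x = %d", nm, cx),
        sprintf("%s/corner_y = %d", nm, cy),
        sprintf("%s/res = 5000", nm))
    }
    parse_geometry(lines)
  })
}
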