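# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env()

# A small 3-chip screen (16x16 grid, 126 designs) used by most module tests.
small_screen <- function(seed = 11) {
  key <- paste0("small", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_screen(screen_config(
      n_chips = 3, high_density_chips = 2, n_designs = 126,
      n_rows = 16, n_cols = 16, seed = seed))
  }
  .fixtures[[key]]
}

# One full-size high-density chip (66x66, 2176 designs) with planted
# artifacts, for truth-registry recall checks.
planted_chip <- function(seed = 5) {
  key <- paste0("planted", seed)
  if (is.null(.fixtures[[key]])) {
    scr <- generate_screen(screen_config(
      n_chips = 1, high_density_chips = 1, n_designs = 2176, seed = seed))
    .fixtures[[key]] <- plant_artifacts(
      scr,
      c(underpopulated = 0.02, overpopulated = 0.02, out_of_focus = 0.02,
        ntoc_extreme = 0.02, replicate_inconsistent = 0.02),
      seed = seed + 1)
  }
  .fixtures[[key]]
}

# The full default nine-chip screen (about 1.2 million cells); generated
# once and shared by the parameter-recovery checks.
default_screen <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- generate_screen(screen_config(seed = 42))
  }
  .fixtures$default
}

truth_units <- function(screen, kind) {
  t <- screen$truth[screen$truth$kind == kind, ]
  unique(paste(t$chip_id, t$row, t$col))
}

unit_keys <- function(units) paste(units$chip_id, units$row, units$col)
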