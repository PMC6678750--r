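# Internal error helpers. Validation failures carry class "tlb_validation_error"
# so the CLI can map them to a distinct exit code.

tlb_stop <- function(msg, class = "tlb_validation_error") {
  abort(msg, class = class)
}

tlb_compute_stop <- function(msg) {
  abort(msg, class = "tlb_computation_error")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Default analysis window: 45-90 degC at 0.1 degC resolution. Eq-style plain
# sums over the grid are only comparable across subjects on a shared grid.
tlb_default_window <- function() {
  list(t_min = 45, t_max = 90, step = 0.1)
}

canonical_grid <- function(t_min = 45, t_max = 90, step = 0.1) {
  seq(t_min, t_max, by = step)
}
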