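# Shared fixtures: published inputs and a fast calibration wrapper.

table1_region <- function() region_inputs()
table2_ubt <- function(...) ubt_spec(...)

# moderate start count keeps the suite fast; the warm starts do the work
quick_calibrate <- function(..., n_starts = 6L) ubt_calibrate(..., n_starts = n_starts)

expect_cascade_equal <- function(a, b, tol = 1e-9) {
  num <- vapply(a$settings, is.numeric, logical(1))
  expect_lt(max(abs(as.matrix(a$settings[num]) - as.matrix(b$settings[num]))), tol)
  expect_lt(max(abs(unlist(a$totals) - unlist(b$totals))), tol)
}
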