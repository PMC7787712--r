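# small in-code fixtures shared across test files

# a clean 5-crab field table in the canonical schema
clean_records <- function() {
  data.frame(
    crab_id = paste0("c", 1:5),
    date = "2019-05-10",
    site = "Shell Hammock",
    sex = c("female", "female", "male", "male", "female"),
    carapace_width_mm = c(10.2, 14.5, 12.0, 16.3, 9.0),
    body_temp_c = c(26.1, 27.3, 25.8, 24.9, 26.5),
    surface_temp_c = c(25.0, 26.2, 25.1, 24.0, 25.7),
    burrow_temp_c = c(22.1, 22.4, 22.0, 21.8, 22.3),
    month = "May",
    stringsAsFactors = FALSE
  )
}

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# exact points on a line y = slope * x + intercept over a spread of x
line_points <- function(slope, intercept, x = seq(-10, 0, length.out = 8)) {
  data.frame(x = x, y = slope * x + intercept)
}

# regulating-regime synthetic axes data: y = b + e_b * x + noise
axes_sample <- function(n, e_b, b_offset, noise_sd, x_range = c(-15, 0)) {
  x <- stats::runif(n, x_range[1], x_range[2])
  data.frame(x = x, y = b_offset + e_b * x + stats::rnorm(n, 0, noise_sd))
}
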