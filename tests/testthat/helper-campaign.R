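# Shared zero-noise training campaign, built once per test run: the 128-run
# fraction decoded to physical units, its virtual-disc responses, and the
# per-response bounds.
.campaign_cache <- new.env(parent = emptyenv())

zero_noise_campaign <- function() {
  if (is.null(.campaign_cache$data)) {
    ranges <- default_parameter_ranges()
    design <- decode_design(fractional_factorial(), ranges)
    responses <- simulate_batch(design)
    .campaign_cache$data <- list(
      ranges = ranges,
      design = design,
      responses = responses,
      bounds = response_bounds(responses)
    )
  }
  .campaign_cache$data
}

# random parameter point inside the design box
random_params <- function(ranges = default_parameter_ranges()) {
  stats::setNames(stats::runif(nrow(ranges), ranges$min, ranges$max),
                  ranges$parameter)
}
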