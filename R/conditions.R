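# Condition classes used across the package.  The CLI maps them to exit
# codes: usage errors -> 1, data/parse/region/alphabet errors -> 2.

stop_usage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("seqmate_usage_error", "seqmate_error")))
}

stop_data <- function(fmt, ..., class = character()) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "seqmate_data_error", "seqmate_error")))
}

stop_alphabet <- function(fmt, ...) {
  stop_data(fmt, ..., class = "seqmate_alphabet_error")
}

stop_region <- function(fmt, ...) {
  stop_data(fmt, ..., class = "seqmate_region_error")
}

stop_parse <- function(fmt, ...) {
  stop_data(fmt, ..., class = "seqmate_parse_error")
}
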