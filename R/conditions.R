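# Structured error conditions. Every user-facing failure mode maps onto one of
# four classes so callers (and the CLI, which translates them into distinct
# exit codes) can react programmatically.

lmg_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "lmg_error"), call = call))
}

#' @noRd
stop_config <- function(msg) lmg_error(msg, "lmg_config_error")

#' @noRd
stop_format <- function(msg) lmg_error(msg, "lmg_format_error")

#' @noRd
stop_contract <- function(msg) lmg_error(msg, "lmg_contract_error")

#' @noRd
stop_domain <- function(msg) lmg_error(msg, "lmg_domain_error")
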