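#' Health states of the psychosis care pathway model
#'
#' The cohort model distinguishes six mutually exclusive health states for
#' people after a first episode of psychosis (FEP): the acute episode itself,
#' symptomatic remission, symptomatic relapse, treatment-resistant
#' schizophrenia, persistent negative symptoms (PNS), and death. Death is
#' absorbing and reachable from every state.
#'
#' @return Character vector of the six state labels, in canonical order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("ACUTE", "REMISSION", "RELAPSE", "RESISTANT", "PNS", "DEAD")
}

#' Default transition structure of the six-state model
#'
#' Returns the adjacency mask of allowed transitions: a 6 x 6 logical matrix
#' indexed by [health_states()]. Self-loops are allowed for every alive state,
#' death is reachable from everywhere, and the clinical arrows are: acute
#' episodes resolve into remission, treatment resistance or persistent
#' negative symptoms; remitted patients can relapse or develop PNS; relapses
#' can re-remit or progress to resistance; resistant patients can respond
#' (e.g. to clozapine) and re-enter remission; PNS patients can relapse.
#' The mask is data, not code: a config can supply its own.
#'
#' @return 6 x 6 logical matrix, `TRUE` where `from -> to` is allowed.
#' @export
default_adjacency <- function() {
  s <- health_states()
  adj <- matrix(FALSE, 6L, 6L, dimnames = list(s, s))
  adj["ACUTE",     c("ACUTE", "REMISSION", "RESISTANT", "PNS", "DEAD")] <- TRUE
  adj["REMISSION", c("REMISSION", "RELAPSE", "PNS", "DEAD")] <- TRUE
  adj["RELAPSE",   c("RELAPSE", "REMISSION", "RESISTANT", "DEAD")] <- TRUE
  adj["RESISTANT", c("RESISTANT", "REMISSION", "DEAD")] <- TRUE
  adj["PNS",       c("PNS", "RELAPSE", "DEAD")] <- TRUE
  adj["DEAD", "DEAD"] <- TRUE
  adj
}

# internal: alive states in canonical order
alive_states <- function() setdiff(health_states(), "DEAD")

# internal: check a vector is a named occupancy/probability vector over states
check_state_vector <- function(x, what = "state vector") {
  s <- health_states()
  if (is.null(names(x)) || !setequal(names(x), s)) {
    stop(what, " must be a numeric vector named by the six health states",
         call. = FALSE)
  }
  x[s]
}
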