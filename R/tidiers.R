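#' Tidy a chemistry history
#'
#' @param x a `chem_history`
#' @param ... unused
#' @return the event log as a tibble (one row per reaction, damage or
#'   escape event)
#' @export
tidy.chem_history <- function(x, ...) {
  tibble::as_tibble(x$events)
}

#' One-row summary of a chemistry history
#'
#' @param x a `chem_history`
#' @param ... unused
#' @return tibble with event counts, the simulated interval and per-primary
#'   damage
#' @export
glance.chem_history <- function(x, ...) {
  ev <- x$events
  nh <- x$n_histories %||% 1L
  tibble::tibble(
    n_histories = nh,
    n_reactions = sum(ev$type == "reaction"),
    n_damage = sum(ev$type == "damage"),
    n_escape = sum(ev$type == "escape"),
    damage_per_primary = sum(ev$type == "damage") / nh,
    start_ps = x$start_time,
    end_ps = x$end_time,
    method = x$method %||% NA_character_
  )
}

#' @export
print.chem_history <- function(x, ...) {
  g <- glance(x)
  cat("<chem_history> ", g$method, " run, ", g$n_histories, " histor",
      if (g$n_histories == 1) "y" else "ies", ", ",
      g$n_reactions, " reactions / ", g$n_damage, " damage / ",
      g$n_escape, " escape events over ",
      format(g$start_ps), "-", format(g$end_ps), " ps\n", sep = "")
  invisible(x)
}
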