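#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a quadripartite partition into one row per region
#'
#' @param x a `quadripartite_partition`.
#' @param ... unused.
#' @return tibble with `region`, `start`, `end`, `length`.
#' @export
tidy.quadripartite_partition <- function(x, ...) {
  if (!x$found) {
    return(tibble(region = "LSC", start = 0L, end = x$genome_length,
                  length = x$genome_length))
  }
  tibble(
    region = c("LSC", "IRa", "SSC", "IRb"),
    start = c(x$lsc[1], x$ira[1], x$ssc[1], x$irb[1]),
    end = c(x$lsc[2], x$ira[2], x$ssc[2], x$irb[2]),
    length = c(x$lsc_length, x$ir_length, x$ssc_length, x$ir_length))
}

#' @rdname tidy.quadripartite_partition
#' @export
glance.quadripartite_partition <- function(x, ...) {
  tibble(found = x$found, genome_length = x$genome_length,
         ir_length = x$ir_length, lsc_length = x$lsc_length,
         ssc_length = x$ssc_length, mismatches = x$mismatches)
}

#' Tidy a Dollo reconstruction into one row per event
#'
#' @param x a `dollo_result`.
#' @param ... unused.
#' @return tibble with `event`, `edge`.
#' @export
tidy.dollo_result <- function(x, ...) {
  gain <- if (x$mode == "single_gain" && !is.na(x$gain_edge)) {
    tibble(event = "gain", edge = x$gain_edge)
  } else tibble(event = character(), edge = character())
  bind_rows(gain, tibble(event = rep("loss", x$loss_count), edge = x$losses$edge))
}

#' @rdname tidy.dollo_result
#' @export
glance.dollo_result <- function(x, ...) {
  tibble(mode = x$mode, gain_edge = x$gain_edge, losses = x$loss_count,
         feasible = x$feasible)
}

#' Tidy a placement scan into long format
#'
#' @param x a `placement_scan`.
#' @param ... unused.
#' @return tibble with `placement`, `edge`, `original`, `character`,
#'   `losses`.
#' @export
tidy.placement_scan <- function(x, ...) {
  chars <- setdiff(names(x), c("placement", "edge", "original", "total"))
  tidyr::pivot_longer(as_tibble(x), dplyr::all_of(chars),
                      names_to = "character", values_to = "losses")
}

#' @rdname tidy.placement_scan
#' @export
glance.placement_scan <- function(x, ...) {
  alt <- filter(as_tibble(x), !.data$original)
  tibble(
    n_placements = nrow(x),
    original_total = x$total[x$original][1],
    alternative_min_total = if (nrow(alt)) min(alt$total) else NA_integer_,
    alternative_max_total = if (nrow(alt)) max(alt$total) else NA_integer_)
}

#' @rdname tidy.placement_scan
#' @export
glance.reversal_scenario <- function(x, ...) {
  tibble(solved = x$solved, distance = x$distance)
}
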