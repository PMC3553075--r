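#' Minimal signed-reversal scenario between two gene orders
#'
#' Breadth-first search over signed block reversals: a move reverses a
#' contiguous block and flips every orientation inside it. Returns the
#' shortest reversal list transforming `order_a` into `order_b`, the model
#' behind small inversion scenarios between plastome arrangements. The
#' search is exhaustive, so it is bounded to short orders (<= 12 genes) and
#' a maximum depth.
#'
#' @param order_a,order_b signed-gene-order tibbles (`symbol`,
#'   `orientation`) over the same symbol set (see [signed_gene_order()]).
#' @param max_depth search bound; deeper scenarios return `solved = FALSE`.
#' @return an object of class `reversal_scenario`: `reversals` tibble
#'   (`step`, `from`, `to` block indices in the evolving order), `solved`,
#'   and `distance` (number of reversals, `NA` if unsolved).
#' @export
reversal_scenario <- function(order_a, order_b, max_depth = 5) {
  a <- as_signed(order_a); b <- as_signed(order_b, symbols = attr(a, "symbols"))
  m <- length(a)
  if (m > 12) abort("exhaustive reversal search is bounded to 12 genes")
  key <- function(p) paste(p, collapse = ",")
  target <- key(b)
  if (key(a) == target) {
    return(new_scenario(tibble(step = integer(), from = integer(),
                               to = integer()), TRUE, 0L))
  }
  moves <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
  frontier <- list(a)
  parents <- new.env(parent = emptyenv())
  assign(key(a), list(NULL, NULL), envir = parents)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (p in frontier) {
      pk <- key(p)
      for (r in seq_len(nrow(moves))) {
        i <- moves[r, "row"]; j <- moves[r, "col"]
        q <- p
        q[i:j] <- -rev(p[i:j])
        qk <- key(q)
        if (!is.null(parents[[qk]])) next
        assign(qk, list(pk, c(i, j)), envir = parents)
        if (qk == target) {
          return(new_scenario(trace_moves(parents, target), TRUE, depth))
        }
        nxt[[length(nxt) + 1]] <- q
      }
    }
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  new_scenario(NULL, FALSE, NA_integer_)
}

as_signed <- function(ord, symbols = NULL) {
  if (!all(c("symbol", "orientation") %in% names(ord))) {
    abort("signed gene order needs columns symbol, orientation")
  }
  if (is.null(symbols)) {
    symbols <- ord$symbol
  } else if (!setequal(symbols, ord$symbol)) {
    abort("the two orders must be over the same symbol set")
  }
  ids <- match(ord$symbol, symbols)
  signed <- ids * ifelse(ord$orientation == "+", 1L, -1L)
  attr(signed, "symbols") <- symbols
  signed
}

trace_moves <- function(parents, target) {
  path <- list()
  k <- target
  repeat {
    entry <- parents[[k]]
    if (is.null(entry[[1]])) break
    path[[length(path) + 1]] <- entry[[2]]
    k <- entry[[1]]
  }
  path <- rev(path)
  tibble(step = seq_along(path),
         from = map_int(path, ~ as.integer(.x[1])),
         to = map_int(path, ~ as.integer(.x[2])))
}

new_scenario <- function(reversals, solved, distance) {
  structure(list(reversals = reversals, solved = solved, distance = distance),
            class = "reversal_scenario")
}

#' @export
print.reversal_scenario <- function(x, ...) {
  if (!x$solved) {
    cat("<reversal_scenario> unsolved within depth bound\n")
  } else {
    cat(sprintf("<reversal_scenario> %d reversal(s)\n", x$distance))
    if (x$distance > 0) print(x$reversals)
  }
  invisible(x)
}

#' Apply a reversal list to a signed gene order
#'
#' Replays the `reversals` of a [reversal_scenario()] so results can be
#' verified against the target order.
#'
#' @param order a signed-gene-order tibble.
#' @param reversals tibble with `from`, `to` block indices.
#' @return the transformed signed-gene-order tibble.
#' @export
apply_reversals <- function(order, reversals) {
  out <- order
  for (r in seq_len(nrow(reversals))) {
    i <- reversals$from[r]; j <- reversals$to[r]
    block <- out[i:j, ]
    block <- block[rev(seq_len(nrow(block))), ]
    block$orientation <- ifelse(block$orientation == "+", "-", "+")
    out[i:j, ] <- block
  }
  out
}
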