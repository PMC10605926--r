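# Round-Robin traffic distribution and communication accounting.
#
# The scheduler cycles a pointer through an ordered list of participant
# nodes, so over any whole number of cycles every node is selected exactly
# equally often -- the fairness property behind using Round-Robin to spread
# transmission cost. The communication log counts rounds, fixed-size
# messages (one model vector of d+1 doubles, 8 bytes per entry) and bytes;
# the volume axis of accuracy-vs-volume curves is bytes / 2^30 gigabytes.

#' Round-Robin scheduler state
#'
#' @param nodes ordered vector of participant node ids (nonempty).
#' @param aggregators vector of server/aggregator node ids (bookkeeping only;
#'   aggregators are not scheduled).
#' @return an object of class `round_robin`: the node list, a `pointer`
#'   (index of the next node to be selected) and per-node send counts.
#' @export
round_robin <- function(nodes, aggregators = character(0)) {
  if (length(nodes) == 0L) stop_("node list must be nonempty")
  structure(list(nodes = nodes, pointer = 1L, aggregators = aggregators,
                 sends = stats::setNames(integer(length(nodes)), as.character(nodes))),
            class = "round_robin")
}

#' Select the next participants in cyclic order
#'
#' Returns the next `k` nodes starting at the pointer, wrapping past the end
#' of the list back to the first node, and advances the pointer by `k`
#' (modulo the number of nodes). Per-node send counts are updated.
#'
#' @param state a [round_robin()] state.
#' @param k number of nodes to select (`>= 1`).
#' @return list with `selected` (vector of `k` node ids) and `state` (the
#'   updated scheduler).
#' @export
next_participants <- function(state, k = 1L) {
  stopifnot(inherits(state, "round_robin"))
  k <- check_count(k, "k")
  nv <- length(state$nodes)
  pos <- ((state$pointer - 1L + seq_len(k) - 1L) %% nv) + 1L
  selected <- state$nodes[pos]
  state$pointer <- ((state$pointer - 1L + k) %% nv) + 1L
  tab <- table(factor(as.character(selected), levels = names(state$sends)))
  state$sends <- state$sends + as.integer(tab)
  list(selected = selected, state = state)
}

#' Communication log
#'
#' @return an object of class `comm_log` with zeroed counters: `rounds`,
#'   `messages`, `bytes`.
#' @export
comm_log <- function() {
  structure(list(rounds = 0L, messages = 0, bytes = 0), class = "comm_log")
}

#' Account one communication round
#'
#' Adds `n_messages` fixed-size messages of `vector_length` 8-byte floating
#' point entries (one model vector including the bias) and advances the round
#' counter. With zero messages only the round counter moves.
#'
#' @param log a [comm_log()].
#' @param n_messages nonnegative message count for the round.
#' @param vector_length entries per message (`d + 1` for a model vector).
#' @return the updated `comm_log`.
#' @export
record_round <- function(log, n_messages, vector_length) {
  stopifnot(inherits(log, "comm_log"))
  if (n_messages < 0 || vector_length < 0) stop_("counts must be nonnegative")
  log$rounds <- log$rounds + 1L
  log$messages <- log$messages + n_messages
  log$bytes <- log$bytes + n_messages * vector_length * 8
  log
}

#' Communication volume in gigabytes
#'
#' `bytes / 2^30` (binary gigabytes).
#'
#' @param log a [comm_log()].
#' @return nonnegative scalar.
#' @export
volume_gigabytes <- function(log) {
  stopifnot(inherits(log, "comm_log"))
  log$bytes / 2^30
}
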