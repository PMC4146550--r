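#' Connect-4 game state for two-action BCI control
#'
#' The standard 6-row x 7-column game, controllable with just two actions:
#' advance the selected-column cursor (with wrap-around from the rightmost
#' to the leftmost column), or drop a coin into the selected column. That
#' two-action reduction is what makes the game playable with a binary
#' motor-imagery BCI.
#'
#' @param to_move which player (1 or 2) moves first.
#' @return A `bci_game` object: `board` (6x7 integer matrix, 0 = empty, row 1
#'   is the bottom), `heights` (coins per column), `to_move`, `cursor`
#'   (0-based selected column), `status` (`"ongoing"`, `"win1"`, `"win2"`,
#'   `"draw"`), `rejected` (count of attempted drops into full columns).
#' @export
new_game <- function(to_move = 1L) {
  structure(list(board = matrix(0L, 6, 7), heights = integer(7),
                 to_move = as.integer(to_move), cursor = 0L,
                 status = "ongoing", rejected = 0L),
            class = "bci_game")
}

#' @export
print.bci_game <- function(x, ...) {
  sym <- c(".", "X", "O")
  for (r in 6:1)
    cat(paste(sym[x$board[r, ] + 1L], collapse = " "), "\n")
  cat(sprintf("status: %s, to_move: %d, cursor: %d\n",
              x$status, x$to_move, x$cursor))
  invisible(x)
}

#' Apply a two-action game move
#'
#' `select_next_column` advances the cursor by one (6 wraps to 0) without
#' changing whose turn it is. `place_coin` drops the mover's coin into the
#' cursor column; a drop into a full column is rejected as a no-op (counted
#' in `rejected`) so the BCI user must re-select -- control errors stay
#' visible rather than being silently remapped.
#'
#' @param game a `bci_game` with `status == "ongoing"`.
#' @param action `"select_next_column"` or `"place_coin"`.
#' @return The updated `bci_game`.
#' @export
apply_action <- function(game, action) {
  stopifnot(inherits(game, "bci_game"))
  if (game$status != "ongoing") stop("game is over (", game$status, ")")
  if (action == "select_next_column") {
    game$cursor <- (game$cursor + 1L) %% 7L
    return(game)
  }
  if (action != "place_coin") stop("unknown action: ", action)
  col <- game$cursor + 1L
  if (game$heights[col] >= 6L) {
    game$rejected <- game$rejected + 1L
    return(game)
  }
  drop_coin(game, col)
}

# internal: drop to_move's coin in 1-based column col (assumed legal)
drop_coin <- function(game, col) {
  row <- game$heights[col] + 1L
  p <- game$to_move
  game$board[row, col] <- p
  game$heights[col] <- row
  if (four_through(game$board, row, col, p))
    game$status <- paste0("win", p)
  else if (all(game$heights == 6L))
    game$status <- "draw"
  game$to_move <- 3L - p
  game
}

# does the coin just placed at (row, col) complete four in a line?
four_through <- function(board, row, col, p) {
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    run <- 1L
    r <- row + d[1]; cl <- col + d[2]
    while (r >= 1L && r <= 6L && cl >= 1L && cl <= 7L && board[r, cl] == p) {
      run <- run + 1L; r <- r + d[1]; cl <- cl + d[2]
    }
    r <- row - d[1]; cl <- col - d[2]
    while (r >= 1L && r <= 6L && cl >= 1L && cl <= 7L && board[r, cl] == p) {
      run <- run + 1L; r <- r - d[1]; cl <- cl - d[2]
    }
    if (run >= 4L) return(TRUE)
  }
  FALSE
}

#' Evaluate a board's status
#'
#' Scans all 69 four-in-a-line windows of the 6x7 board (24 horizontal, 21
#' vertical, 24 diagonal).
#'
#' @param board 6x7 integer matrix (0/1/2), row 1 at the bottom.
#' @return `"win1"`, `"win2"`, `"draw"` (full board, no four), or
#'   `"ongoing"`.
#' @export
winner_check <- function(board) {
  w <- connect4_windows()
  for (p in 1:2) {
    hit <- colSums(matrix(board[w] == p, nrow = 4)) == 4
    if (any(hit)) return(paste0("win", p))
  }
  if (all(board != 0L)) "draw" else "ongoing"
}

# 4 x 69 matrix of linear board indices, one column per window; memoized
connect4_windows <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    idx <- function(r, c) (c - 1L) * 6L + r
    wins <- list()
    for (r in 1:6) for (c in 1:4) wins[[length(wins) + 1]] <- idx(r, c:(c + 3))
    for (c in 1:7) for (r in 1:3) wins[[length(wins) + 1]] <- idx(r:(r + 3), c)
    for (r in 1:3) for (c in 1:4) {
      wins[[length(wins) + 1]] <- idx(r:(r + 3), c:(c + 3))
      wins[[length(wins) + 1]] <- idx((r + 3):r, c:(c + 3))
    }
    cache <<- matrix(unlist(wins), nrow = 4)
    cache
  }
})

#' Baseline computer opponent
#'
#' The win/block/random policy: play an immediately winning column if one
#' exists (lowest index first); otherwise block an opponent's immediate win
#' (lowest index -- a double threat can only be blocked once, which is what
#' lets a random player win games at all); otherwise pick a uniformly random
#' legal column.
#'
#' @param game an ongoing `bci_game`; the move is for `game$to_move`.
#' @return 1-based column index.
#' @export
heuristic_move <- function(game) {
  stopifnot(game$status == "ongoing")
  legal <- which(game$heights < 6L)
  if (length(legal) == 0) stop("no legal move")
  me <- game$to_move; opp <- 3L - me
  for (col in legal)
    if (four_through(game$board, game$heights[col] + 1L, col, me)) return(col)
  for (col in legal)
    if (four_through(game$board, game$heights[col] + 1L, col, opp)) return(col)
  legal[sample.int(length(legal), 1L)]
}

#' Uniformly random legal move
#'
#' @inheritParams heuristic_move
#' @return 1-based column index, uniform over legal columns.
#' @export
random_move <- function(game) {
  legal <- which(game$heights < 6L)
  legal[sample.int(length(legal), 1L)]
}

#' Simulate Connect-4 matches between two column-policies
#'
#' Plays `n` independent games, alternating who moves first, and tabulates
#' outcome percentages. Policies receive the game and return a column; use
#' [random_move()] and [heuristic_move()] for the random-control baseline
#' that calibrates what fraction of games pure chance wins.
#'
#' @param n number of games.
#' @param policy_a,policy_b functions `game -> column` for players 1 and 2.
#' @param seed RNG seed (reproducible percentages).
#' @return List `winA`, `winB`, `draw` (percentages summing to 100) and
#'   `n`.
#' @examples
#' \donttest{
#' simulate_matches(200, random_move, heuristic_move, seed = 1)
#' }
#' @export
simulate_matches <- function(n, policy_a, policy_b, seed = 1) {
  set.seed(seed)
  tally <- c(winA = 0L, winB = 0L, draw = 0L)
  for (g in seq_len(n)) {
    game <- new_game(to_move = if (g %% 2L == 1L) 1L else 2L)
    while (game$status == "ongoing") {
      col <- if (game$to_move == 1L) policy_a(game) else policy_b(game)
      game <- drop_coin(game, col)
    }
    tally[switch(game$status, win1 = "winA", win2 = "winB", draw = "draw")] <-
      tally[switch(game$status, win1 = "winA", win2 = "winB", draw = "draw")] + 1L
  }
  out <- as.list(100 * tally / n)
  out$n <- n
  out
}
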