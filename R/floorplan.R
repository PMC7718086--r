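#' Construct a floorplan graph
#'
#' A floorplan is the spatial model the household simulator walks on: a
#' connected, undirected graph of rooms, each room carrying one or more
#' motion sensors, with a single traversal distance in meters between
#' adjacent rooms. Deployments in the emulated platform carried 5 to 30
#' remote sensors per home, and the constructor enforces that range.
#'
#' @param rooms character vector of unique room identifiers.
#' @param sensors named list mapping every room to a character vector of
#'   sensor identifiers (at least one per room); a sensor may belong to only
#'   one room.
#' @param adjacency two-column character matrix (or data.frame) of adjacent
#'   room pairs; interpreted as undirected edges, so each pair needs to be
#'   listed only once. The resulting graph must be connected.
#' @param room_distance meters walked per traversal between adjacent rooms.
#' @return An object of class `floorplan`.
#' @examples
#' fp <- make_floorplan(n_rooms = 6)
#' length(all_sensors(fp))
#' @export
floorplan <- function(rooms, sensors, adjacency, room_distance = 5) {
  stopifnot(is.character(rooms), length(rooms) >= 1L)
  if (anyDuplicated(rooms))
    stop("duplicate room identifiers", call. = FALSE)
  if (!is.list(sensors) || !setequal(names(sensors), rooms))
    stop("'sensors' must be a named list with one entry per room",
         call. = FALSE)
  if (any(lengths(sensors) < 1L))
    stop("every room needs at least one sensor", call. = FALSE)
  sens <- unlist(sensors, use.names = FALSE)
  if (anyDuplicated(sens))
    stop("a sensor may belong to exactly one room; duplicated: ",
         paste(unique(sens[duplicated(sens)]), collapse = ", "),
         call. = FALSE)
  if (length(sens) < 5L || length(sens) > 30L)
    stop("total sensor count must be between 5 and 30, got ", length(sens),
         call. = FALSE)
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2L)
    stop("'adjacency' must have two columns", call. = FALSE)
  mode(adjacency) <- "character"
  if (!all(adjacency %in% rooms))
    stop("adjacency refers to unknown rooms", call. = FALSE)
  if (any(adjacency[, 1] == adjacency[, 2]))
    stop("self-adjacent rooms are not allowed", call. = FALSE)
  stopifnot(is.numeric(room_distance), room_distance > 0)

  # neighbor list (symmetric closure of the edge list)
  nbr <- lapply(rooms, function(r) {
    sort(unique(c(adjacency[adjacency[, 1] == r, 2],
                  adjacency[adjacency[, 2] == r, 1])))
  })
  names(nbr) <- rooms

  # connectivity via BFS from the first room
  seen <- rooms[1]
  frontier <- rooms[1]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(nbr[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (length(seen) < length(rooms))
    stop("floorplan graph is not connected; unreachable rooms: ",
         paste(setdiff(rooms, seen), collapse = ", "), call. = FALSE)

  structure(list(rooms = rooms, sensors = sensors, adjacency = adjacency,
                 neighbors = nbr, room_distance = as.numeric(room_distance)),
            class = "floorplan")
}

#' Build a simple corridor-style floorplan
#'
#' Convenience constructor used by the simulator defaults and tests: rooms in
#' a chain with one shortcut edge (so walks are not forced back and forth),
#' `sensors_per_room` sensors in each room.
#'
#' @param n_rooms number of rooms (default 8).
#' @param sensors_per_room sensors installed per room (default 1).
#' @param room_distance meters per traversal between adjacent rooms.
#' @return A `floorplan` object with sensors named `sensor_1 ... sensor_K`.
#' @export
make_floorplan <- function(n_rooms = 8L, sensors_per_room = 1L,
                           room_distance = 5) {
  n_rooms <- as.integer(n_rooms)
  stopifnot(n_rooms >= 2L, sensors_per_room >= 1L)
  rooms <- sprintf("room_%02d", seq_len(n_rooms))
  k <- 0L
  sensors <- lapply(rooms, function(r) {
    ids <- sprintf("sensor_%d", k + seq_len(sensors_per_room))
    k <<- k + as.integer(sensors_per_room)
    ids
  })
  names(sensors) <- rooms
  adjacency <- cbind(rooms[-n_rooms], rooms[-1])
  if (n_rooms >= 3L)  # shortcut closing a triangle at the start of the chain
    adjacency <- rbind(adjacency, c(rooms[1], rooms[3]))
  floorplan(rooms, sensors, adjacency, room_distance)
}

#' @rdname floorplan
#' @param x a `floorplan`.
#' @export
all_sensors <- function(x) {
  stopifnot(inherits(x, "floorplan"))
  unlist(x$sensors, use.names = FALSE)
}

#' @export
print.floorplan <- function(x, ...) {
  cat("<floorplan> ", length(x$rooms), " rooms, ",
      length(all_sensors(x)), " sensors, ",
      nrow(x$adjacency), " edges, ", x$room_distance,
      " m per traversal\n", sep = "")
  invisible(x)
}
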