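# Readers/writers for STL, PLY, OBJ.

test_that("STL round trips (ASCII and binary) reproduce the cube", {
  m <- make_cube()
  for (binary in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".stl")
    write_mesh(m, path, binary = binary)
    back <- load_mesh(path)
    expect_equal(nrow(back$vertices), 8L)
    expect_equal(nrow(back$faces), 12L)
    expect_true(back$closed)
    expect_equal(sort(back$vertices[, 1]), sort(m$vertices[, 1]),
                 tolerance = 1e-6)
    unlink(path)
  }
})

test_that("PLY and OBJ round trips preserve geometry", {
  m <- fx_coarse()$mesh
  for (fmt in c("ply", "obj")) {
    for (binary in if (fmt == "ply") c(FALSE, TRUE) else FALSE) {
      path <- tempfile(fileext = paste0(".", fmt))
      write_mesh(m, path, binary = binary)
      back <- load_mesh(path)
      expect_equal(nrow(back$vertices), nrow(m$vertices))
      expect_equal(nrow(back$faces), nrow(m$faces))
      expect_true(back$closed)
      expect_lt(max(abs(back$vertices - m$vertices)), 1e-8)
      unlink(path)
    }
  }
})

test_that("I/O errors are informative", {
  expect_error(load_mesh(tempfile(fileext = ".ply")), "not found")
  path <- tempfile(fileext = ".xyz")
  writeLines("nonsense", path)
  expect_error(load_mesh(path), "unsupported")
  unlink(path)
})
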