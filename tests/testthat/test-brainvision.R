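test_that("writer/reader round-trip preserves samples and markers", {
  ep <- fixture_participant()
  cont <- epochs_to_continuous(subset_trials(ep, 1:4))
  td <- withr::local_tempdir()

  write_brainvision(cont, file.path(td, "f32"), "IEEE_FLOAT_32")
  r <- read_brainvision(file.path(td, "f32.vhdr"))
  expect_equal(r$sfreq, cont$sfreq)
  expect_identical(r$channel_labels, cont$channel_labels)
  expect_identical(r$events, cont$events)
  # float32 storage: exact after one quantisation; a second round trip is
  # bit-identical
  write_brainvision(r, file.path(td, "f32b"), "IEEE_FLOAT_32")
  r2 <- read_brainvision(file.path(td, "f32b.vhdr"))
  expect_identical(r2$data, r$data)
  expect_lt(max(abs(r$data - cont$data)), 1e-4 * max(abs(cont$data)) + 1e-6)

  write_brainvision(cont, file.path(td, "i16"), "INT_16", resolution = 0.1)
  ri <- read_brainvision(file.path(td, "i16.vhdr"))
  expect_lte(max(abs(ri$data - cont$data)), 0.05 + 1e-12) # half a bit at 0.1 uV/bit
})

test_that("hand-built marker fixture parses with correct sample indices", {
  td <- withr::local_tempdir()
  n <- 100
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "[Common Infos]",
               "DataFile=toy.eeg", "MarkerFile=toy.vmrk",
               "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
               "NumberOfChannels=2", "SamplingInterval=10000",
               "[Binary Infos]", "BinaryFormat=INT_16",
               "[Channel Infos]", "Ch1=C3,,0.5,µV", "Ch2=C4,,0.5,µV"),
             file.path(td, "toy.vhdr"))
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,20240101120000000000",
               "Mk2=Stimulus,S 10,10,1,0",
               "Mk3=Stimulus,S 20,40,1,0",
               "Mk4=Stimulus,S 30,90,1,0"),
             file.path(td, "toy.vmrk"))
  con <- file(file.path(td, "toy.eeg"), "wb")
  writeBin(as.integer(rep(c(2L, -4L), n)), con, size = 2, endian = "little")
  close(con)

  r <- read_brainvision(file.path(td, "toy.vhdr"))
  expect_equal(r$sfreq, 100)
  expect_equal(nrow(r$events), 3)
  expect_equal(r$events$sample, c(10L, 40L, 90L))
  expect_equal(r$events$marker, c("S 10", "S 20", "S 30"))
  expect_equal(dim(r$data), c(2L, n))
  expect_equal(unique(r$data[1, ]), 1)   # 2 bits x 0.5 uV
  expect_equal(unique(r$data[2, ]), -2)
})

test_that("format inconsistencies raise informative errors", {
  ep <- fixture_participant()
  cont <- epochs_to_continuous(subset_trials(ep, 1:2))
  td <- withr::local_tempdir()
  write_brainvision(cont, file.path(td, "a"), "INT_16")

  # truncate the data file so its length no longer divides into channels
  sz <- file.size(file.path(td, "a.eeg"))
  con <- file(file.path(td, "a.eeg"), "r+b")
  truncate_at <- sz - 2
  seek(con, truncate_at)
  truncate(con)
  close(con)
  expect_error(read_brainvision(file.path(td, "a.vhdr")), "not a multiple")

  # missing companion data file
  file.remove(file.path(td, "a.eeg"))
  expect_error(read_brainvision(file.path(td, "a.vhdr")), "not found")

  # unknown binary format
  hdr <- readLines(file.path(td, "a.vhdr"))
  hdr <- sub("BinaryFormat=INT_16", "BinaryFormat=INT_32", hdr)
  writeLines(hdr, file.path(td, "b.vhdr"))
  file.create(file.path(td, "a.eeg"))
  hdr2 <- sub("DataFile=a.eeg", "DataFile=a.eeg", hdr)
  writeLines(hdr2, file.path(td, "b.vhdr"))
  expect_error(read_brainvision(file.path(td, "b.vhdr")), "BinaryFormat")
})
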