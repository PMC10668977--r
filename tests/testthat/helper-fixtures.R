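# Shared fixture builders. Everything is generated at test time.

small_phantom <- function(seed = 1L, juxtapleural = FALSE, size = 128L) {
  nod <- if (juxtapleural) {
    list(phantom_nodule(c(0, 0), radius = 8, juxtapleural = TRUE))
  } else NULL
  make_phantom(phantom_spec(image_size = c(size, size), seed = seed,
                            nodules = nod))
}

# a disc mask for geometry tests
disc <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

# write a single-slice DICOM with pydicom (the independent implementation),
# so the package's reader is checked against an external writer
write_dicom_with_pydicom <- function(path, mat, intercept = -1024, slope = 1,
                                     implicit = FALSE, rescale = TRUE) {
  pixfile <- tempfile(fileext = ".txt")
  write.table(mat, pixfile, row.names = FALSE, col.names = FALSE)
  script <- sprintf('
import sys
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian, generate_uid

mat = np.loadtxt(%s, ndmin=2).astype(np.int16)
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
meta.MediaStorageSOPInstanceUID = generate_uid()
meta.TransferSyntaxUID = %s
ds = Dataset()
ds.file_meta = meta
ds.SOPClassUID = meta.MediaStorageSOPClassUID
ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
ds.Modality = "CT"
ds.Rows, ds.Columns = mat.shape
ds.BitsAllocated = 16
ds.BitsStored = 16
ds.HighBit = 15
ds.PixelRepresentation = 1
ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
ds.PixelSpacing = ["0.7", "0.7"]
if %s:
    ds.RescaleIntercept = "%s"
    ds.RescaleSlope = "%s"
ds.PixelData = mat.tobytes()
ds.save_as(%s, enforce_file_format=True)
',
    deparse(pixfile),
    if (implicit) "ImplicitVRLittleEndian" else "ExplicitVRLittleEndian",
    if (rescale) "True" else "False",
    format(intercept), format(slope), deparse(path))
  out <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(path)) stop("pydicom fixture generation failed:\n",
                               paste(out, collapse = "\n"))
  invisible(path)
}
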