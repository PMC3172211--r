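>syn001
ANMQVMVNNPGWRMAMQKCYGPFYDYWSPKSWVVLFFWSPDWYGQDNTQGywmTYDVAIQ
LIVRILHNAKvYRPEYSPYYDCA
>syn002
VHKHMTNLTYDEKWHDSDTPySMSAGPILFIFVWSHLCPRIYFLPATLKCPAHVGHMTFN
KrqwISAYYLIHDDFF
>syn003
QGWPGSHTMSynsDPTTAMYAGHSVMKDTTMKKDMMNCCYYQTSEFCRRQTHVNQMMARV
GFHPAHGHL
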