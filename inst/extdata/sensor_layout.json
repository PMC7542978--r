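{
  "labels": ["MCP_T", "MCP_I", "MCP_M", "MCP_R", "MCP_L",
             "PIP_T", "PIP_I", "PIP_M", "PIP_R", "PIP_L",
             "A1", "A2", "A3", "A4", "PArch", "Tcross",
             "P1", "P2", "P3", "P4", "P5",
             "QH_w", "QH_x", "QH_y", "QH_z",
             "QW_w", "QW_x", "QW_y", "QW_z"],
  "roles": {
    "MCP_T": "thumb_bend_MCP",
    "MCP_I": "finger_bend_MCP", "MCP_M": "finger_bend_MCP",
    "MCP_R": "finger_bend_MCP", "MCP_L": "finger_bend_MCP",
    "PIP_T": "thumb_bend_IP",
    "PIP_I": "finger_bend_PIP", "PIP_M": "finger_bend_PIP",
    "PIP_R": "finger_bend_PIP", "PIP_L": "finger_bend_PIP",
    "A1": "abduction", "A2": "abduction", "A3": "abduction", "A4": "abduction",
    "PArch": "palm_arch", "Tcross": "thumb_cross",
    "P1": "pressure", "P2": "pressure", "P3": "pressure",
    "P4": "pressure", "P5": "pressure",
    "QH_w": "orientation", "QH_x": "orientation",
    "QH_y": "orientation", "QH_z": "orientation",
    "QW_w": "orientation", "QW_x": "orientation",
    "QW_y": "orientation", "QW_z": "orientation"
  },
  "relevant19": ["MCP_T", "MCP_I", "MCP_M", "MCP_R", "MCP_L",
                 "PIP_T", "PIP_I", "PIP_M", "PIP_R", "PIP_L",
                 "A1", "A2", "A3", "A4", "PArch", "Tcross",
                 "P1", "P2", "P3"],
  "graph12": ["MCP_T", "MCP_I", "MCP_M", "MCP_R", "MCP_L",
              "PIP_T", "PIP_I", "PIP_M", "PIP_R", "PIP_L",
              "PArch", "Tcross"]
}
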