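parameter,sex,age_group,low,high,unit
hemoglobin,M,infant_0_6m,9.5,18,g/dL
hemoglobin,M,child_6m_12y,11,15.5,g/dL
hemoglobin,M,over_12y,13,17.5,g/dL
hemoglobin,F,infant_0_6m,9.5,18,g/dL
hemoglobin,F,child_6m_12y,11,15.5,g/dL
hemoglobin,F,over_12y,12,16,g/dL
mcv,M,infant_0_6m,77.5,111.5,fL
mcv,M,child_6m_12y,74,89.5,fL
mcv,M,over_12y,80,100,fL
mcv,F,infant_0_6m,77.5,111.5,fL
mcv,F,child_6m_12y,74,89.5,fL
mcv,F,over_12y,80,100,fL
reticulocytes,M,infant_0_6m,61,134,1e9/L
reticulocytes,M,child_6m_12y,24,114,1e9/L
reticulocytes,M,over_12y,29,95,1e9/L
reticulocytes,F,infant_0_6m,67,142,1e9/L
reticulocytes,F,child_6m_12y,40,162,1e9/L
reticulocytes,F,over_12y,27,91,1e9/L
platelets,M,infant_0_6m,145,450,1e9/L
platelets,M,child_6m_12y,145,450,1e9/L
platelets,M,over_12y,145,450,1e9/L
platelets,F,infant_0_6m,145,450,1e9/L
platelets,F,child_6m_12y,145,450,1e9/L
platelets,F,over_12y,145,450,1e9/L
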