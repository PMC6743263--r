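"role","action"
"site_crc","upload_images"
"site_crc","run_deid"
"site_crc","raise_query"
"site_crc","answer_query"
"site_crc","read_images"
"uploader","upload_images"
"uploader","run_deid"
"uploader","answer_query"
"qc_staff","run_qc"
"qc_staff","record_manual_qc"
"qc_staff","raise_query"
"qc_staff","answer_query"
"qc_staff","read_images"
"central_reviewer","read_images"
"central_reviewer","read_measurement"
"central_reviewer","write_measurement"
"central_reviewer","read_form"
"central_reviewer","write_form"
"central_reviewer","sign_record"
"central_reviewer","answer_query"
"adjudicator","read_images"
"adjudicator","read_measurement"
"adjudicator","read_form"
"adjudicator","write_form"
"adjudicator","sign_record"
"adjudicator","answer_query"
"project_manager","read_images"
"project_manager","read_measurement"
"project_manager","read_form"
"project_manager","read_audit"
"project_manager","raise_query"
"project_manager","close_query"
"project_manager","escalate_query"
"project_manager","export_data"
"project_manager","sign_record"
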